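#' Parameter-uncertainty distribution specifications
#'
#' A distribution-spec table attaches an uncertainty distribution to a
#' resource-item quantity (\code{target = "quantity"}) or branch probability
#' (\code{target = "probability"}). Supported families and their parameters
#' (columns \code{p1..p4}): \code{point} (p1 = value, or the model's base
#' value when NA), \code{uniform} (p1 = min, p2 = max), \code{triangular}
#' (p1 = min, p2 = max, p3 = mode), \code{beta} (p1 = alpha, p2 = beta),
#' \code{gamma} (p1 = shape, p2 = rate). The support must respect the
#' parameter's domain: probabilities in [0,1], quantities non-negative.
#'
#' @param specs Data frame of distribution specs.
#' @param model A \code{pathway_model} (resolves parameter references).
#' @return \code{validate_dist_specs}: the validated spec table, invisibly.
#' @export
validate_dist_specs <- function(specs, model) {
  err <- function(...) stop(sprintf(...), call. = FALSE)
  ok_fam <- c("point", "uniform", "triangular", "beta", "gamma")
  bad <- setdiff(specs$family, ok_fam)
  if (length(bad)) err("unknown distribution family: %s",
                       paste(bad, collapse = ", "))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    known <- if (s$target == "probability") model$probs$id else model$items$id
    if (!s$parameter_ref %in% known)
      err("distribution spec references unknown %s '%s'",
          s$target, s$parameter_ref)
    prob <- s$target == "probability"
    switch(s$family,
      uniform = , triangular = {
        if (is.na(s$p1) || is.na(s$p2) || s$p1 > s$p2)
          err("%s: need p1 <= p2", s$parameter_ref)
        if (s$p1 < 0 || (prob && s$p2 > 1))
          err("%s: support outside parameter domain", s$parameter_ref)
        if (s$family == "triangular" &&
            (is.na(s$p3) || s$p3 < s$p1 || s$p3 > s$p2))
          err("%s: triangular mode outside [min, max]", s$parameter_ref)
      },
      beta = {
        if (is.na(s$p1) || is.na(s$p2) || s$p1 <= 0 || s$p2 <= 0)
          err("%s: beta needs alpha > 0 and beta > 0", s$parameter_ref)
      },
      gamma = {
        if (is.na(s$p1) || is.na(s$p2) || s$p1 <= 0 || s$p2 <= 0)
          err("%s: gamma needs shape > 0 and rate > 0", s$parameter_ref)
        if (prob) err("%s: gamma support exceeds [0,1]", s$parameter_ref)
      },
      point = NULL)
  }
  invisible(specs)
}

# n draws for one spec row; each parameter uses its own generator stream
# derived from (seed, parameter index) so that appending parameters to the
# spec table never perturbs the draws of existing ones.
draw_spec <- function(s, n, base) {
  switch(s$family,
    point = rep(if (is.na(s$p1)) base else s$p1, n),
    uniform = stats::runif(n, s$p1, s$p2),
    triangular = {
      u <- stats::runif(n)
      fc <- (s$p3 - s$p1) / (s$p2 - s$p1)
      ifelse(u < fc,
             s$p1 + sqrt(u * (s$p2 - s$p1) * (s$p3 - s$p1)),
             s$p2 - sqrt((1 - u) * (s$p2 - s$p1) * (s$p2 - s$p3)))
    },
    beta = stats::rbeta(n, s$p1, s$p2),
    gamma = stats::rgamma(n, shape = s$p1, rate = s$p2))
}

param_seed <- function(seed, i) (abs(seed) + 7919L * i) %% 2147483629L

draw_matrices <- function(specs, model, n, seed) {
  base_q <- stats::setNames(model$items$quantity, model$items$id)
  base_p <- stats::setNames(model$probs$value, model$probs$id)
  Q <- list(); P <- list()
  if (nrow(specs)) {
    for (i in seq_len(nrow(specs))) {
      s <- specs[i, ]
      set.seed(param_seed(seed, i))
      base <- if (s$target == "probability") base_p[[s$parameter_ref]]
              else base_q[[s$parameter_ref]]
      col <- draw_spec(s, n, base)
      if (s$target == "probability") P[[s$parameter_ref]] <- col
      else Q[[s$parameter_ref]] <- col
    }
  }
  list(Q = if (length(Q)) as.data.frame(Q) else NULL,
       P = if (length(P)) as.data.frame(P) else NULL)
}

#' Draw one parameter set from distribution specs
#'
#' Returns the full parameter set (all item quantities and branch
#' probabilities), with spec'd parameters redrawn from their distributions
#' and all others at their base values. Identical seeds give identical
#' draws; an all-point spec table returns the base parameter set exactly.
#'
#' @inheritParams validate_dist_specs
#' @param seed Integer seed.
#' @return List with named vectors \code{quantities} and
#'   \code{probabilities}.
#' @export
sample_parameters <- function(specs, model, seed = 1L) {
  validate_dist_specs(specs, model)
  d <- draw_matrices(specs, model, 1L, seed)
  q <- stats::setNames(model$items$quantity, model$items$id)
  p <- stats::setNames(model$probs$value, model$probs$id)
  if (!is.null(d$Q)) q[colnames(d$Q)] <- unlist(d$Q[1, , drop = TRUE])
  if (!is.null(d$P)) p[colnames(d$P)] <- unlist(d$P[1, , drop = TRUE])
  list(quantities = q, probabilities = p)
}

#' Probabilistic sensitivity analysis by seeded Monte Carlo
#'
#' Redraws every spec'd parameter from its distribution in each iteration
#' and re-evaluates the expected per-woman cost, yielding a sample of
#' expected costs. The evaluation is vectorised over iterations via the
#' model's outcome-path decomposition (the expected cost is multilinear in
#' the parameters); point-mass spec tables reproduce the deterministic total
#' exactly, and identical seeds give bit-identical results.
#'
#' @inheritParams evaluate_expected_cost
#' @param specs Distribution-spec table (see
#'   \code{\link{validate_dist_specs}}).
#' @param n_sims Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed.
#' @return A \code{psa_result}: samples, their mean and the 2.5th/97.5th
#'   centile pseudo confidence interval (type-7 quantiles).
#' @export
run_psa <- function(model, strategy, setting, specs, n_sims = 10000L,
                    seed = 1L) {
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  validate_dist_specs(specs, model)
  d <- draw_matrices(specs, model, n_sims, seed)
  paths <- compile_paths(model, strategy, setting)
  base_p <- stats::setNames(model$probs$value, model$probs$id)

  # per-iteration item costs: constant unless the item's quantity is drawn
  base_cost <- item_cost_table(model, setting)
  cost_col <- function(id) {
    if (!is.null(d$Q) && id %in% colnames(d$Q)) {
      row <- model$items[model$items$id == id, , drop = FALSE]
      v <- item_unit_value(model, row$unit_cost_ref)
      unit <- model$unit_costs$unit[model$unit_costs$id == row$unit_cost_ref]
      q <- d$Q[[id]]
      if (identical(unit, "per_hour")) q / 60 * v else q * v
    } else rep(base_cost[[id]], n_sims)
  }
  prob_col <- function(ref)
    if (!is.null(d$P) && ref %in% colnames(d$P)) d$P[[ref]]
    else rep(base_p[[ref]], n_sims)

  item_ids <- unique(unlist(lapply(paths, `[[`, "items")))
  cost_cache <- lapply(stats::setNames(item_ids, item_ids), cost_col)

  samples <- numeric(n_sims)
  for (pa in paths) {
    pr <- rep(1, n_sims)
    for (f in pa$factors) {
      pr <- pr * if (f$type == "residual") {
        res <- rep(1, n_sims)
        for (r in f$refs) res <- res - prob_col(r)
        pmax(res, 0)
      } else prob_col(f$refs)
    }
    if (length(pa$items)) {
      cost <- rep(0, n_sims)
      for (id in pa$items) cost <- cost + cost_cache[[id]]
      samples <- samples + pr * cost
    }
  }
  ci <- pseudo_ci(samples)
  structure(list(samples = samples, n_sims = n_sims, seed = seed,
                 mean = mean(samples), ci_low = ci[[1]], ci_high = ci[[2]],
                 strategy = strategy, setting = setting),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "PSA (%d simulations, seed %d): %s / %s\n  mean GBP %.2f (pseudo-CI %.2f to %.2f)\n",
    x$n_sims, x$seed, x$strategy, x$setting,
    x$mean, x$ci_low, x$ci_high))
  invisible(x)
}

#' @describeIn run_psa \code{simulate} method for \code{pathway_model}:
#'   runs the PSA and returns the \code{psa_result}.
#' @param object A \code{pathway_model}.
#' @param nsim Number of simulations.
#' @param ... Unused.
#' @export
simulate.pathway_model <- function(object, nsim = 10000L, seed = 1L, ...,
                                   strategy, setting, specs)
  run_psa(object, strategy, setting, specs, n_sims = nsim, seed = seed)

#' Empirical centile pseudo confidence interval
#'
#' The 2.5th and 97.5th empirical centiles of a Monte Carlo cost sample,
#' computed with type-7 quantiles (linear interpolation between order
#' statistics) — stated explicitly because centile conventions differ.
#'
#' @param samples Non-empty numeric vector.
#' @param levels Two probabilities (default 0.025 and 0.975).
#' @return Numeric vector of the two centiles.
#' @export
pseudo_ci <- function(samples, levels = c(0.025, 0.975)) {
  if (!length(samples)) stop("empty sample vector", call. = FALSE)
  unname(stats::quantile(samples, probs = levels, type = 7))
}

#' Deterministic sensitivity analysis over informant scenarios
#'
#' Re-evaluates the model under each scenario's resource-use overrides (one
#' scenario per informant) and compares against the base (mean-input) total.
#'
#' @inheritParams evaluate_expected_cost
#' @param scenarios List of scenarios, each a list with \code{id} and
#'   \code{overrides} (named vector, item id -> alternative quantity).
#' @return Data frame (scenario, total) with the base total first; the
#'   attribute \code{"max_abs_deviation"} holds the largest absolute
#'   deviation of any scenario from the base.
#' @export
run_dsa <- function(model, strategy, setting, scenarios) {
  if (!length(scenarios)) stop("need at least one scenario", call. = FALSE)
  base <- evaluate_expected_cost(model, strategy, setting)$total
  rows <- data.frame(scenario = "base", total = base,
                     stringsAsFactors = FALSE)
  for (sc in scenarios) {
    ov <- sc$overrides
    if (length(ov) && any(ov < 0))
      stop("override quantities must be >= 0", call. = FALSE)
    tot <- if (length(ov))
      evaluate_expected_cost(model, strategy, setting, quantities = ov)$total
    else base
    rows <- rbind(rows, data.frame(scenario = sc$id, total = tot,
                                   stringsAsFactors = FALSE))
  }
  attr(rows, "max_abs_deviation") <- max(abs(rows$total[-1] - base))
  rows
}

#' Monte Carlo convergence check
#'
#' Computes the running mean and pseudo-CI of one PSA sample stream at
#' increasing checkpoints; the table is a prefix-consistent view of a single
#' seeded stream. A run is flagged converged at a checkpoint when the
#' running mean moved by no more than \code{tolerance} since the previous
#' checkpoint.
#'
#' @inheritParams run_psa
#' @param checkpoints Ascending vector of simulation counts.
#' @param tolerance Convergence tolerance on the running mean in GBP
#'   (default 0.10).
#' @return Data frame with columns \code{n}, \code{mean}, \code{ci_low},
#'   \code{ci_high}, \code{converged}.
#' @export
convergence_check <- function(model, strategy, setting, specs, seed = 1L,
                              checkpoints = c(100, 1000, 10000),
                              tolerance = 0.10) {
  if (is.unsorted(checkpoints, strictly = TRUE))
    stop("checkpoints must be ascending", call. = FALSE)
  res <- run_psa(model, strategy, setting, specs,
                 n_sims = max(checkpoints), seed = seed)
  # the first checkpoint is judged against its own half-prefix mean
  prev <- mean(res$samples[seq_len(max(1, ceiling(checkpoints[1] / 2)))])
  out <- lapply(checkpoints, function(n) {
    s <- res$samples[seq_len(n)]
    ci <- pseudo_ci(s)
    row <- data.frame(n = n, mean = mean(s), ci_low = ci[[1]],
                      ci_high = ci[[2]],
                      converged = abs(mean(s) - prev) <= tolerance)
    prev <<- mean(s)
    row
  })
  do.call(rbind, out)
}

#' Write a PSA report across strategies and settings
#'
#' CSV mirroring the published probabilistic-analysis table: one row per
#' strategy x setting with mean and pseudo-CI (2 dp).
#'
#' @param model A \code{pathway_model}.
#' @param specs Distribution-spec table.
#' @param path Output CSV path.
#' @param n_sims,seed Passed to \code{\link{run_psa}}.
#' @param provenance Named character vector of comment headers.
#' @return Invisibly, the path.
#' @export
write_psa_report <- function(model, specs, path, n_sims = 10000L, seed = 1L,
                             provenance = character(0)) {
  rows <- list()
  for (se in names(model$settings)) for (st in names(model$strategies)) {
    r <- run_psa(model, st, se, specs, n_sims = n_sims, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      strategy = st, setting = se, mean = round_money(r$mean),
      ci_low = round_money(r$ci_low), ci_high = round_money(r$ci_high),
      stringsAsFactors = FALSE)
  }
  write_report_csv(do.call(rbind, rows), path,
                   c(provenance, n_sims = as.character(n_sims),
                     seed = as.character(seed)))
}
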