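#' Seeded random pathway models with known expected cost
#'
#' Generates random chance-node trees whose exact expected cost is
#' accumulated analytically during construction, independently of the
#' recursive evaluator — the construction-time total serves as an oracle for
#' the engine. Branch probabilities are drawn from a symmetric Dirichlet
#' (concentration configurable); activity costs are uniform over
#' \code{cost_range}.
#'
#' @param config List with \code{seed}, \code{depth} (maximum chance-node
#'   depth, >= 0), \code{branching} (maximum branches per chance node,
#'   >= 2), \code{cost_range} (length-2 numeric, min <= max) and
#'   \code{probability_concentration} (Dirichlet concentration, > 0).
#' @return List with \code{model} (a \code{pathway_model}, strategy
#'   \code{"ALL"}, setting \code{"base"}) and \code{expected_cost} (the
#'   construction-time analytic total).
#' @export
generate_random_model <- function(config) {
  stopifnot(config$depth >= 0, config$branching >= 2,
            length(config$cost_range) == 2,
            config$cost_range[1] <= config$cost_range[2])
  conc <- if (is.null(config$probability_concentration)) 1
          else config$probability_concentration
  set.seed(config$seed)

  items <- list(); probs <- list(); counter <- new.env()
  counter$item <- 0L; counter$node <- 0L; counter$prob <- 0L

  new_items <- function(n) {
    costs <- stats::runif(n, config$cost_range[1], config$cost_range[2])
    ids <- vapply(seq_len(n), function(i) {
      counter$item <- counter$item + 1L
      sprintf("it%03d", counter$item)
    }, character(1))
    for (i in seq_len(n))
      items[[length(items) + 1]] <<- data.frame(
        id = ids[i], stage = sample(PATHWAY_STAGES, 1),
        description = "synthetic activity item", quantity = costs[i],
        unit_cost_ref = "unit_gbp", settings = "base",
        printed_cost_gbp = NA_real_, assumed = FALSE,
        vans_per_trust = NA_real_, weeks_between_moves = NA_real_,
        screens_per_week = NA_real_, stringsAsFactors = FALSE)
    list(ids = ids, cost = sum(costs))
  }

  act_node <- function() {
    a <- new_items(sample(1:3, 1))
    list(node = list(type = "act", component = NULL,
                     items = as.list(a$ids)),
         ev = a$cost)
  }

  build <- function(depth) {
    if (depth == 0 || stats::runif(1) < 0.3) return(act_node())
    nb <- sample(2:config$branching, 1)
    w <- stats::rgamma(nb, shape = conc)
    p <- w / sum(w)
    counter$node <- counter$node + 1L
    nid <- sprintf("nd%03d", counter$node)
    branches <- list(); ev <- 0
    for (i in seq_len(nb)) {
      child <- if (stats::runif(1) < 0.2) NULL else build(depth - 1)
      if (i < nb) {
        counter$prob <- counter$prob + 1L
        pid <- sprintf("p%03d", counter$prob)
        probs[[length(probs) + 1]] <<- data.frame(
          id = pid, value = p[i], description = "synthetic branch",
          source = "generator", stringsAsFactors = FALSE)
        pref <- pid
      } else pref <- "~"
      branches[[i]] <- list(p = pref,
                            child = if (is.null(child)) NULL else child$node)
      ev <- ev + p[i] * (if (is.null(child)) 0 else child$ev)
    }
    list(node = list(type = "chance", id = nid, component = NULL,
                     branches = branches),
         ev = ev)
  }

  n_blocks <- sample(1:3, 1)
  children <- list(); total <- 0
  for (i in seq_len(n_blocks)) {
    blk <- build(config$depth)
    children[[i]] <- blk$node
    total <- total + blk$ev
  }

  unit_costs <- data.frame(
    id = "unit_gbp", description = "synthetic direct cost, 1 GBP per unit",
    value_gbp = 1, unit = "per_item", source = "generator",
    price_year = 2021L, stringsAsFactors = FALSE)
  structure_list <- list(
    stages = PATHWAY_STAGES,
    strategies = list(ALL = list(components = character(0),
                                 risk_set = list())),
    settings = list(base = list(exclude_items = character(0),
                                exclude_components = character(0),
                                substitute = list())),
    root = list(type = "seq", children = children))
  model <- build_model(unit_costs = unit_costs,
                       items = do.call(rbind, items),
                       probabilities = if (length(probs))
                         do.call(rbind, probs)
                       else data.frame(id = character(0), value = numeric(0),
                                       description = character(0),
                                       source = character(0)),
                       structure = structure_list)
  list(model = model, expected_cost = total)
}

#' Synthetic informant resource-use scenarios
#'
#' Emulates per-informant variation in interview-reported resource use:
#' each informant's reported quantities are the base quantities perturbed by
#' multiplicative log-normal noise with the stated coefficient of variation
#' (mean-corrected, so informant means converge to the base quantities).
#' Durations are positive and right-skewed, which motivates the log-normal
#' family.
#'
#' @param items Resource-item data frame (see
#'   \code{\link{paper_resource_items}}); rows without a stored quantity
#'   (amortised items) are left untouched.
#' @param coefficient_of_variation Relative spread of informant reports,
#'   >= 0.
#' @param n_informants Number of informant scenarios to generate, >= 1.
#' @param seed Integer seed.
#' @return List of scenarios usable with \code{\link{run_dsa}}: each has an
#'   \code{id} and an \code{overrides} named vector of quantities.
#' @export
perturb_resource_use <- function(items, coefficient_of_variation,
                                 n_informants, seed = 1L) {
  cv <- coefficient_of_variation
  if (cv < 0) stop("coefficient_of_variation must be >= 0", call. = FALSE)
  if (n_informants < 1) stop("n_informants must be >= 1", call. = FALSE)
  keep <- !is.na(items$quantity)
  sdlog <- sqrt(log(1 + cv^2))
  set.seed(seed)
  lapply(seq_len(n_informants), function(i) {
    f <- stats::rlnorm(sum(keep), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    list(id = sprintf("informant_%d", i),
         overrides = stats::setNames(items$quantity[keep] * f,
                                     items$id[keep]))
  })
}
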