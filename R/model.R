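#' Build a validated risk-stratification pathway model
#'
#' Assembles the unit-cost ledger, resource items, branch probabilities and
#' pathway structure into an immutable, validated \code{pathway_model}. The
#' pathway is a tree whose internal nodes are chance nodes (branches weighted
#' by named probability parameters, with \code{"~"} marking the complement
#' branch that receives the residual probability) and whose leaves are
#' activities, i.e. bundles of resource items. Strategies select component
#' subtrees and a risk-probability set; setting profiles (trial vs routine
#' NHS delivery) exclude or substitute items.
#'
#' @param path Directory containing a fixture bundle
#'   (\code{unit_costs.csv}, \code{resource_items.csv},
#'   \code{probabilities.csv}, \code{pathway.json}); if supplied, the other
#'   arguments are read from it.
#' @param unit_costs,items,probabilities Data frames in the fixture-bundle
#'   schemas (see \code{\link{paper_unit_costs}} and friends).
#' @param structure Pathway structure list (see \code{\link{paper_pathway}}).
#' @return An object of class \code{pathway_model}. The attribute
#'   \code{"validation"} carries a report listing any items defined in the
#'   ledger but never referenced by the pathway.
#' @examples
#' m <- paper_model()
#' predict(m, strategy = "TC", setting = "trial")
#' @export
build_model <- function(path = NULL, unit_costs = NULL, items = NULL,
                        probabilities = NULL, structure = NULL) {
  if (!is.null(path)) {
    rcsv <- function(f) {
      fp <- file.path(path, f)
      if (!file.exists(fp))
        stop(sprintf("fixture file missing: %s", f), call. = FALSE)
      utils::read.csv(fp, stringsAsFactors = FALSE)
    }
    unit_costs <- rcsv("unit_costs.csv")
    items <- rcsv("resource_items.csv")
    probabilities <- rcsv("probabilities.csv")
    fp <- file.path(path, "pathway.json")
    if (!file.exists(fp))
      stop("fixture file missing: pathway.json", call. = FALSE)
    structure <- jsonlite::read_json(fp, simplifyVector = FALSE)
    structure$stages <- unlist(structure$stages)
    for (s in names(structure$strategies))
      structure$strategies[[s]]$components <-
        unlist(structure$strategies[[s]]$components)
    for (s in names(structure$settings)) {
      structure$settings[[s]]$exclude_items <-
        as.character(unlist(structure$settings[[s]]$exclude_items))
      structure$settings[[s]]$exclude_components <-
        as.character(unlist(structure$settings[[s]]$exclude_components))
    }
  }
  model <- structure(
    list(unit_costs = unit_costs, items = items, probs = probabilities,
         stages = structure$stages, strategies = structure$strategies,
         settings = structure$settings, root = structure$root),
    class = "pathway_model")
  attr(model, "validation") <- validate_model(model)
  model
}

validate_model <- function(model) {
  err <- function(...) stop(sprintf(...), call. = FALSE)
  uc <- model$unit_costs; it <- model$items; pr <- model$probs
  if (anyDuplicated(uc$id)) err("duplicate unit cost id")
  if (anyDuplicated(it$id)) err("duplicate resource item id")
  if (anyDuplicated(pr$id)) err("duplicate probability id")
  bad_unit <- setdiff(uc$unit, UNIT_KINDS)
  if (length(bad_unit))
    err("unknown unit kind: %s", paste(bad_unit, collapse = ", "))
  if (any(uc$value_gbp < 0)) err("negative unit cost value")
  dangling <- setdiff(it$unit_cost_ref, uc$id)
  if (length(dangling))
    err("resource item references missing unit cost: %s",
        paste(dangling, collapse = ", "))
  amort <- !is.na(it$vans_per_trust)
  if (any(it$quantity[!amort] < 0, na.rm = TRUE) ||
      any(is.na(it$quantity[!amort])))
    err("resource item quantity must be a non-negative number")
  if (any(pr$value < 0 | pr$value > 1))
    err("probability outside [0,1]: %s",
        paste(pr$id[pr$value < 0 | pr$value > 1], collapse = ", "))

  # walk the tree: collect node ids, item refs, probability refs
  seen_nodes <- character(0); used_items <- character(0)
  walk <- function(node) {
    if (is.null(node)) return(invisible())
    if (node$type == "seq") {
      for (ch in node$children) walk(ch)
    } else if (node$type == "chance") {
      if (node$id %in% seen_nodes) err("node reachable twice: %s", node$id)
      seen_nodes <<- c(seen_nodes, node$id)
      residuals <- 0
      for (b in node$branches) {
        pref <- b$p
        if (identical(pref, "~")) residuals <- residuals + 1
        else if (!startsWith(pref, "@") && !pref %in% pr$id)
          err("unknown probability parameter: %s (node %s)", pref, node$id)
        walk(b$child)
      }
      if (residuals > 1) err("node %s has multiple complement branches", node$id)
      if (residuals == 0) {
        direct <- vapply(node$branches, function(b)
          if (startsWith(b$p, "@")) NA_real_ else pr$value[pr$id == b$p],
          numeric(1))
        if (!anyNA(direct) && abs(sum(direct) - 1) > 1e-9)
          err("branch probabilities at node %s sum to %.6f, not 1",
              node$id, sum(direct))
      }
    } else if (node$type == "act") {
      ids <- as.character(unlist(node$items))
      missing <- setdiff(ids, it$id)
      if (length(missing))
        err("activity references missing item: %s",
            paste(missing, collapse = ", "))
      used_items <<- c(used_items, ids)
    } else err("unknown node type: %s", node$type)
    invisible()
  }
  walk(model$root)

  for (s in names(model$strategies)) {
    rs <- model$strategies[[s]]$risk_set
    missing <- setdiff(unlist(rs), pr$id)
    if (length(missing))
      err("strategy %s risk set references missing probability: %s",
          s, paste(missing, collapse = ", "))
  }
  for (s in names(model$settings)) {
    sub <- model$settings[[s]]$substitute
    bad <- setdiff(c(names(sub), unlist(sub)), it$id)
    if (length(bad))
      err("setting %s substitution references missing item: %s",
          s, paste(bad, collapse = ", "))
  }
  used_items <- unique(c(used_items,
                         unlist(lapply(model$settings, function(s)
                           unlist(s$substitute)))))
  list(unused_items = setdiff(it$id, used_items))
}

# Deterministic cost of one resource item row, honouring printed-cost
# overrides and the amortisation rule; `q` overrides the stored quantity.
item_unit_value <- function(model, ref)
  model$unit_costs$value_gbp[model$unit_costs$id == ref]

item_cost_row <- function(model, row, q = NULL) {
  if (!is.na(row$printed_cost_gbp) && is.null(q))
    return(row$printed_cost_gbp)
  v <- item_unit_value(model, row$unit_cost_ref)
  if (!is.na(row$vans_per_trust))
    return(amortized_event_cost(v, row$vans_per_trust,
                                row$weeks_between_moves,
                                row$screens_per_week))
  if (is.null(q)) q <- row$quantity
  unit <- model$unit_costs$unit[model$unit_costs$id == row$unit_cost_ref]
  if (identical(unit, "per_hour")) time_cost(q, v) else quantity_cost(q, v)
}

# Apply a setting profile to an activity's item ids: drop excluded ones,
# apply substitutions. Returns resolved item ids (possibly empty).
resolve_items <- function(setting_profile, ids) {
  out <- character(0)
  for (id in ids) {
    sub <- setting_profile$substitute[[id]]
    if (!is.null(sub)) id <- sub
    if (id %in% setting_profile$exclude_items) next
    out <- c(out, id)
  }
  out
}

resolve_prob_ref <- function(model, strategy_def, ref) {
  if (startsWith(ref, "@")) {
    ref <- strategy_def$risk_set[[ref]]
    if (is.null(ref)) stop(sprintf("unmapped risk probability %s", ref),
                           call. = FALSE)
  }
  ref
}

get_strategy <- function(model, strategy) {
  sd <- model$strategies[[strategy]]
  if (is.null(sd))
    stop(sprintf("unknown strategy '%s' (valid: %s)", strategy,
                 paste(names(model$strategies), collapse = ", ")),
         call. = FALSE)
  sd
}

get_setting <- function(model, setting) {
  sp <- model$settings[[setting]]
  if (is.null(sp))
    stop(sprintf("unknown setting '%s' (valid: %s)", setting,
                 paste(names(model$settings), collapse = ", ")),
         call. = FALSE)
  sp
}

node_included <- function(node, components)
  is.null(node$component) || node$component %in% components ||
    length(components) == 0

#' Expected per-woman cost of a strategy in a setting
#'
#' Computes the expected cost by recursive descent over the pathway tree:
#' each activity contributes (probability that it fires) x (activity cost),
#' accumulated per pathway stage. Branch probabilities, item quantities and
#' unit costs can be overridden, which is how the deterministic and
#' probabilistic sensitivity analyses re-evaluate the model.
#'
#' @param model A \code{pathway_model}.
#' @param strategy Strategy id (e.g. \code{"TC"}, \code{"TC_VBD"},
#'   \code{"TC_VBD_SNP"} in the packaged fixture).
#' @param setting Setting id (e.g. \code{"trial"} or \code{"nhs"}).
#' @param quantities Optional named vector overriding item quantities
#'   (overridden items are recomputed from quantity x unit cost even when a
#'   printed per-woman cost would otherwise take precedence).
#' @param probabilities Optional named vector overriding branch probability
#'   parameters.
#' @return A \code{cost_breakdown}: list with \code{per_stage} (named
#'   expected cost per stage), \code{total}, a per-item detail data frame,
#'   and the strategy/setting ids.
#' @export
evaluate_expected_cost <- function(model, strategy, setting,
                                   quantities = NULL, probabilities = NULL) {
  sd <- get_strategy(model, strategy)
  sp <- get_setting(model, setting)
  components <- setdiff(sd$components, sp$exclude_components)
  pvals <- stats::setNames(model$probs$value, model$probs$id)
  if (!is.null(probabilities)) {
    unknown <- setdiff(names(probabilities), names(pvals))
    if (length(unknown))
      stop(sprintf("unknown probability override: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    pvals[names(probabilities)] <- probabilities
  }
  if (!is.null(quantities)) {
    unknown <- setdiff(names(quantities), model$items$id)
    if (length(unknown))
      stop(sprintf("unknown quantity override: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }

  per_stage <- stats::setNames(numeric(length(model$stages)), model$stages)
  detail <- list()

  branch_prob <- function(node, b) {
    if (identical(b$p, "~")) {
      direct <- vapply(node$branches, function(x)
        if (identical(x$p, "~")) 0
        else pvals[[resolve_prob_ref(model, sd, x$p)]], numeric(1))
      max(0, 1 - sum(direct))
    } else pvals[[resolve_prob_ref(model, sd, b$p)]]
  }

  walk <- function(node, p) {
    if (is.null(node) || !node_included(node, components)) return(invisible())
    if (node$type == "seq") {
      for (ch in node$children) walk(ch, p)
    } else if (node$type == "chance") {
      for (b in node$branches) walk(b$child, p * branch_prob(node, b))
    } else {
      ids <- resolve_items(sp, as.character(unlist(node$items)))
      for (id in ids) {
        row <- model$items[model$items$id == id, , drop = FALSE]
        q <- if (!is.null(quantities) && id %in% names(quantities))
          quantities[[id]] else NULL
        cost <- item_cost_row(model, row, q)
        stage <- row$stage
        if (!stage %in% names(per_stage)) per_stage[stage] <- 0
        per_stage[stage] <<- per_stage[stage] + p * cost
        detail[[length(detail) + 1]] <<- data.frame(
          item = id, stage = stage, probability = p, cost = cost,
          expected_cost = p * cost, stringsAsFactors = FALSE)
      }
    }
    invisible()
  }
  walk(model$root, 1)

  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(item = character(0), stage = character(0),
               probability = numeric(0), cost = numeric(0),
               expected_cost = numeric(0))
  structure(list(strategy = strategy, setting = setting,
                 per_stage = per_stage, total = sum(per_stage),
                 items = detail),
            class = "cost_breakdown")
}

#' Exhaustively enumerate pathway outcomes
#'
#' Brute-force oracle for \code{\link{evaluate_expected_cost}}: lists every
#' root-to-leaf combination of chance-node outcomes with its probability and
#' total cost. Probabilities sum to 1 and the probability-weighted cost
#' equals the recursive evaluator's total (to numerical precision).
#'
#' @inheritParams evaluate_expected_cost
#' @return Data frame with columns \code{path}, \code{probability},
#'   \code{cost}.
#' @export
enumerate_outcomes <- function(model, strategy, setting,
                               quantities = NULL, probabilities = NULL) {
  paths <- compile_paths(model, strategy, setting)
  pvals <- stats::setNames(model$probs$value, model$probs$id)
  if (!is.null(probabilities)) pvals[names(probabilities)] <- probabilities
  costs <- item_cost_table(model, setting, quantities)
  out <- lapply(paths, function(pa) {
    pr <- 1
    for (f in pa$factors)
      pr <- pr * if (f$type == "residual") max(0, 1 - sum(pvals[f$refs]))
                 else pvals[[f$refs]]
    data.frame(path = pa$label, probability = pr,
               cost = sum(costs[pa$items]), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Deterministic cost of every item under a setting (named vector); quantity
# overrides force recomputation from quantity x unit price.
item_cost_table <- function(model, setting, quantities = NULL) {
  costs <- stats::setNames(numeric(nrow(model$items)), model$items$id)
  for (i in seq_len(nrow(model$items))) {
    row <- model$items[i, , drop = FALSE]
    q <- if (!is.null(quantities) && row$id %in% names(quantities))
      quantities[[row$id]] else NULL
    costs[row$id] <- item_cost_row(model, row, q)
  }
  costs
}

# Flatten the pruned pathway into outcome paths with symbolic probability
# factors; shared by the enumeration oracle and the vectorised PSA.
compile_paths <- function(model, strategy, setting) {
  sd <- get_strategy(model, strategy)
  sp <- get_setting(model, setting)
  components <- setdiff(sd$components, sp$exclude_components)

  rec <- function(node) {
    empty <- list(list(label = "", factors = list(), items = character(0)))
    if (is.null(node) || !node_included(node, components)) return(empty)
    if (node$type == "act") {
      ids <- resolve_items(sp, as.character(unlist(node$items)))
      return(list(list(label = "", factors = list(), items = ids)))
    }
    if (node$type == "chance") {
      direct <- vapply(Filter(function(b) !identical(b$p, "~"),
                              node$branches),
                       function(b) resolve_prob_ref(model, sd, b$p),
                       character(1))
      out <- list()
      for (b in node$branches) {
        f <- if (identical(b$p, "~"))
          list(type = "residual", refs = direct)
        else list(type = "direct", refs = resolve_prob_ref(model, sd, b$p))
        lab <- paste0(node$id, "=", if (identical(b$p, "~")) "~" else f$refs)
        for (sub in rec(b$child))
          out[[length(out) + 1]] <- list(
            label = paste0(lab, if (nzchar(sub$label)) "/" else "", sub$label),
            factors = c(list(f), sub$factors),
            items = sub$items)
      }
      return(out)
    }
    # sequence: cartesian product of children outcome sets
    acc <- empty
    for (ch in node$children) {
      sub <- rec(ch)
      if (length(sub) == 1 && !length(sub[[1]]$factors)) {
        acc <- lapply(acc, function(a) {
          a$items <- c(a$items, sub[[1]]$items); a
        })
      } else {
        acc <- unlist(lapply(acc, function(a) lapply(sub, function(s)
          list(label = paste0(a$label,
                              if (nzchar(a$label) && nzchar(s$label)) "/" else "",
                              s$label),
               factors = c(a$factors, s$factors),
               items = c(a$items, s$items)))),
          recursive = FALSE)
      }
    }
    acc
  }
  rec(model$root)
}

#' Stage shares of a cost breakdown
#'
#' @param breakdown A \code{cost_breakdown} with positive total.
#' @return Named vector of percentages summing to 100.
#' @export
stage_shares <- function(breakdown) {
  if (!inherits(breakdown, "cost_breakdown"))
    stop("stage_shares expects a cost_breakdown", call. = FALSE)
  if (breakdown$total <= 0)
    stop("stage shares undefined for a zero-total breakdown", call. = FALSE)
  100 * breakdown$per_stage / breakdown$total
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Expected per-woman cost: strategy %s, setting %s\n",
              x$strategy, x$setting))
  st <- x$per_stage[x$per_stage > 0]
  for (s in names(st))
    cat(sprintf("  %-24s GBP %8.2f\n", s, round_money(st[[s]])))
  cat(sprintf("  %-24s GBP %8.2f\n", "total", round_money(x$total)))
  invisible(x)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("Risk-stratification pathway cost model\n")
  cat(sprintf("  %d resource items, %d unit costs, %d probability parameters\n",
              nrow(x$items), nrow(x$unit_costs), nrow(x$probs)))
  cat(sprintf("  strategies: %s\n", paste(names(x$strategies), collapse = ", ")))
  cat(sprintf("  settings:   %s\n", paste(names(x$settings), collapse = ", ")))
  un <- attr(x, "validation")$unused_items
  if (length(un)) cat(sprintf("  unused items: %s\n", paste(un, collapse = ", ")))
  invisible(x)
}

#' @export
summary.pathway_model <- function(object, ...) {
  grid <- sapply(names(object$settings), function(se)
    sapply(names(object$strategies), function(st)
      evaluate_expected_cost(object, st, se)$total))
  structure(list(grid = grid), class = "summary.pathway_model")
}

#' @export
print.summary.pathway_model <- function(x, ...) {
  cat("Expected per-woman cost (GBP) by strategy and setting\n")
  print(round_money(x$grid))
  invisible(x)
}

#' @describeIn evaluate_expected_cost \code{predict} method: evaluate the
#'   expected cost for one strategy/setting pair.
#' @param object A \code{pathway_model}.
#' @param ... Unused.
#' @export
predict.pathway_model <- function(object, strategy, setting, ...)
  evaluate_expected_cost(object, strategy, setting)

#' Write strategy-by-setting and per-stage cost reports
#'
#' \code{write_table3_report} writes the strategy x setting grid of expected
#' per-woman costs (2 dp); \code{write_stage_report} writes the per-stage
#' breakdown for every strategy/setting pair. Both prepend provenance
#' comment lines (\code{# key: value}) readable back with
#' \code{read.csv(comment.char = "#")}.
#'
#' @param model A \code{pathway_model}.
#' @param path Output CSV path.
#' @param provenance Named character vector written as comment headers.
#' @return Invisibly, the path.
#' @export
write_table3_report <- function(model, path, provenance = character(0)) {
  grid <- summary(model)$grid
  df <- data.frame(strategy = rownames(grid),
                   round_money(grid), check.names = FALSE)
  write_report_csv(df, path, provenance)
}

#' @rdname write_table3_report
#' @export
write_stage_report <- function(model, path, provenance = character(0)) {
  rows <- list()
  for (se in names(model$settings)) for (st in names(model$strategies)) {
    br <- evaluate_expected_cost(model, st, se)
    rows[[length(rows) + 1]] <- data.frame(
      strategy = st, setting = se, stage = names(br$per_stage),
      expected_cost = round_money(unname(br$per_stage)),
      stringsAsFactors = FALSE)
  }
  write_report_csv(do.call(rbind, rows), path, provenance)
}

write_report_csv <- function(df, path, provenance = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
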