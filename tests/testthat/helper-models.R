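# Shared fixtures, built in code once per test run.

fixture_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_model(paper_fixture_path())
    m
  }
})

fixture_specs <- local({
  s <- NULL
  function() {
    if (is.null(s))
      s <<- utils::read.csv(file.path(paper_fixture_path(),
                                      "distributions.csv"),
                            stringsAsFactors = FALSE)
    s
  }
})

fixture_schedule <- function() paper_batch_schedule()

# Point-mass version of the fixture distribution table (degenerate PSA).
point_specs <- function() {
  s <- fixture_specs()
  s$family <- "point"
  s[c("p1", "p2", "p3", "p4")] <- NA_real_
  s
}

# Minimal hand-built model: one chance node (p = 0.5) over two activities
# costing 10 and 20 GBP, plus optional unconditional activities.
toy_model <- function(p = 0.5, costs = c(10, 20), unconditional = numeric(0)) {
  n_items <- length(costs) + length(unconditional)
  items <- data.frame(
    id = sprintf("a%d", seq_len(n_items)),
    stage = "invitation", description = "toy",
    quantity = c(costs, unconditional), unit_cost_ref = "gbp",
    settings = "base", printed_cost_gbp = NA_real_, assumed = FALSE,
    vans_per_trust = NA_real_, weeks_between_moves = NA_real_,
    screens_per_week = NA_real_, stringsAsFactors = FALSE)
  branch_items <- sprintf("a%d", seq_along(costs))
  uncond_items <- sprintf("a%d", length(costs) + seq_along(unconditional))
  children <- list(list(type = "chance", id = "n1", component = NULL,
                        branches = list(
                          list(p = "p1", child = list(type = "act",
                                                      component = NULL,
                                                      items = list(branch_items[1]))),
                          list(p = "~", child = list(type = "act",
                                                     component = NULL,
                                                     items = list(branch_items[2]))))))
  if (length(unconditional))
    children <- c(children, list(list(type = "act", component = NULL,
                                      items = as.list(uncond_items))))
  build_model(
    unit_costs = data.frame(id = "gbp", description = "one pound per unit",
                            value_gbp = 1, unit = "per_item",
                            source = "test", price_year = 2021L,
                            stringsAsFactors = FALSE),
    items = items,
    probabilities = data.frame(id = "p1", value = p, description = "toy",
                               source = "test", stringsAsFactors = FALSE),
    structure = list(stages = PATHWAY_STAGES,
                     strategies = list(ALL = list(components = character(0),
                                                  risk_set = list())),
                     settings = list(base = list(exclude_items = character(0),
                                                 exclude_components = character(0),
                                                 substitute = list())),
                     root = list(type = "seq", children = children)))
}

# Published reference values asserted across the suite (2021 GBP).
PRINTED_TABLE3 <- matrix(
  c(16.45, 21.82, 102.22,
    4.68, 6.64, 86.30),
  nrow = 3, dimnames = list(c("TC", "TC_VBD", "TC_VBD_SNP"),
                            c("trial", "nhs")))
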