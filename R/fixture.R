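#' The packaged breast-screening risk-stratification cost fixture
#'
#' In-memory constructors for the parameter set of the costed
#' risk-stratification pathway: the unit-cost ledger, per-stage resource
#' items, branch probabilities, pathway structure, parameter-uncertainty
#' distributions, the SNP-genotyping batch schedule and the national rollout
#' scenario. Every number is a published point value (2021 GBP) except rows
#' flagged \code{reconstructed = TRUE}, which re-create detail that is only
#' available in aggregate (the genotyping consumable schedule and all
#' uncertainty-distribution families), and the one row flagged
#' \code{assumed = TRUE} (the telephone follow-up of unclear paper surveys,
#' which has a published branch probability but no published cost).
#'
#' \code{make_paper_fixture()} writes the bundle to disk as plain-text
#' CSV/JSON files; \code{\link{build_model}} reads such a bundle back.
#'
#' @name paper_fixture
NULL

#' Pathway stage labels, in pathway order
#' @export
PATHWAY_STAGES <- c("invitation", "questionnaire", "density",
                    "density_implementation", "snp", "risk_letter",
                    "consultation")

#' @rdname paper_fixture
#' @return \code{paper_unit_costs}: data frame forming the unit-cost ledger
#'   (columns id, description, value_gbp, unit, source, price_year).
#' @export
paper_unit_costs <- function() {
  data.frame(
    id = c("sheet", "stamp", "admin_hour", "fellow_hour", "consultant_hour",
           "nurse_hour", "snp_staff_hour", "volpara_fee", "van_move",
           "snp_consumables_full"),
    description = c(
      "Printing, per sheet of paper",
      "Second-class stamp",
      "Administrator (grade 4 scientific staff proxy), per hour",
      "Research fellow (grade 7 scientific staff proxy), per hour",
      "Medical consultant, per hour",
      "Band 5 nurse, per hour",
      "Grade 5 scientific staff running SNP test, per hour",
      "Automated breast-density measurement, per image",
      "Uninstall/reinstall internet aerial, per van move",
      "SNP test consumables incl. array chips, per-sample share, full batch"),
    value_gbp = c(0.12, 0.66, 35, 62, 123, 41, 41, 1.15, 500, 51.73),
    unit = c("per_sheet", "per_stamp", "per_hour", "per_hour", "per_hour",
             "per_hour", "per_hour", "per_measurement", "per_move",
             "per_item"),
    source = c("published stationery cost, inflated to 2021",
               "2021 UK second-class stamp",
               "PSSRU 2021", "PSSRU 2021", "PSSRU 2021", "PSSRU 2021",
               "PSSRU 2021", "supplier communication",
               "supplier communication",
               "published full-batch aggregate"),
    price_year = 2021L,
    stringsAsFactors = FALSE)
}

#' @rdname paper_fixture
#' @return \code{paper_resource_items}: data frame of resource items
#'   consumed at each pathway stage. \code{quantity} is in the unit's
#'   natural measure (minutes for per-hour units, counts otherwise).
#'   \code{printed_cost_gbp}, where not NA, is a published per-woman cost
#'   that takes precedence over recomputation from quantity x unit cost.
#'   The amortisation columns are filled only for the aerial row.
#' @export
paper_resource_items <- function() {
  it <- function(id, stage, description, quantity, ref, settings = "trial,nhs",
                 printed = NA_real_, assumed = FALSE,
                 vans = NA_real_, weeks = NA_real_, screens = NA_real_)
    data.frame(id = id, stage = stage, description = description,
               quantity = quantity, unit_cost_ref = ref, settings = settings,
               printed_cost_gbp = printed, assumed = assumed,
               vans_per_trust = vans, weeks_between_moves = weeks,
               screens_per_week = screens, stringsAsFactors = FALSE)
  rbind(
    it("inv_print", "invitation", "Printing study invitation and information, 7 sheets",
       7, "sheet", "trial"),
    it("inv_staff", "invitation", "Printing letter and filling envelope, 5 min",
       5, "admin_hour", "trial"),
    it("inv_post", "invitation", "Posting the invitation, 1 stamp",
       1, "stamp", "trial"),
    it("q_print", "questionnaire", "Printing paper survey, 4 sheets", 4, "sheet"),
    it("q_post", "questionnaire", "Return postage for paper survey, 1 stamp", 1, "stamp"),
    it("q_entry", "questionnaire", "Manual transfer of paper survey to CRA system, 21.25 min",
       21.25, "admin_hour"),
    it("q_phone", "questionnaire", "Telephone follow-up of unclear paper survey, 5 min (assumed)",
       5, "admin_hour", assumed = TRUE),
    it("volpara", "density", "Automated breast-density measurement, 1 per woman",
       1, "volpara_fee"),
    it("vol_followup", "density_implementation",
       "Research fellow follows up failed image transfer, 6.25 min",
       6.25, "fellow_hour", "trial"),
    it("birads_read", "density_implementation",
       "Consultant manual BI-RADS read after transfer failure, 1 min",
       1, "consultant_hour", "trial"),
    it("aerial", "density_implementation",
       "Aerial uninstall/reinstall amortised over screens",
       NA_real_, "van_move", "trial", vans = 2, weeks = 3, screens = 580),
    it("saliva_collection", "snp", "Nurse collects saliva sample, 3.5 min",
       3.5, "nurse_hour"),
    it("snp_staff", "snp", "Staff time running SNP test, full-batch per-sample share",
       38.39, "snp_staff_hour", printed = 25.25),
    it("snp_consumables", "snp", "SNP consumables incl. chips, full-batch per-sample share",
       1, "snp_consumables_full"),
    it("letter_retrieve", "risk_letter",
       "Retrieving risk data from CRA and transferring to collator, 7.5 min",
       7.5, "admin_hour", "trial"),
    it("letter_print", "risk_letter", "Printing risk letter, 2 sheets", 2, "sheet"),
    it("letter_fill", "risk_letter", "Printing letter and filling envelope, 2 min",
       2, "admin_hour"),
    it("letter_post", "risk_letter", "Posting the risk letter, 1 stamp", 1, "stamp"),
    it("organize_appt", "consultation", "Organising risk appointment, 2.25 min",
       2.25, "admin_hour"),
    it("risk_pack", "consultation", "Collating risk pack for clinician, 17.5 min",
       17.5, "admin_hour", "trial"),
    it("consult_high", "consultation", "Consultant-led high-risk consultation, 30 min",
       30, "consultant_hour", "trial"),
    it("consult_mod", "consultation", "Consultant-led moderate-risk consultation, 20 min",
       20, "consultant_hour", "trial"),
    it("consult_high_nhs", "consultation", "Nurse-led high-risk consultation, 30 min",
       30, "nurse_hour", "nhs"),
    it("consult_mod_nhs", "consultation", "Nurse-led moderate-risk consultation, 20 min",
       20, "nurse_hour", "nhs"))
}

#' @rdname paper_fixture
#' @return \code{paper_probabilities}: data frame of branch probabilities
#'   (id, value, description, source).
#' @export
paper_probabilities <- function() {
  pr <- function(id, value, description, source = "study interviews")
    data.frame(id = id, value = value, description = description,
               source = source, stringsAsFactors = FALSE)
  rbind(
    pr("p_paper", 0.05, "Completes the risk questionnaire on paper rather than online"),
    pr("p_followup", 0.35, "Paper survey unclear, needs telephone follow-up"),
    pr("p_fail", 0.325, "Mammography image fails to transfer for density measurement"),
    pr("p_birads", 0.045, "Failed image needs manual BI-RADS reading"),
    pr("p_high_tc", 0.0147, "Predicted high risk, questionnaire-only strategy", "published risk distribution"),
    pr("p_mod_tc", 0.0846, "Predicted moderate risk, questionnaire-only strategy", "published risk distribution"),
    pr("p_high_vbd", 0.05, "Predicted high risk, questionnaire + breast density", "published risk distribution"),
    pr("p_mod_vbd", 0.112, "Predicted moderate risk, questionnaire + breast density", "published risk distribution"),
    pr("p_high_snp", 0.074, "Predicted high risk, questionnaire + density + SNP", "published risk distribution"),
    pr("p_mod_snp", 0.105, "Predicted moderate risk, questionnaire + density + SNP", "published risk distribution"),
    pr("p_attend_high", 0.7429, "High-risk woman organises a risk appointment", "published uptake"),
    pr("p_attend_mod", 0.7312, "Moderate-risk woman organises a risk appointment", "published uptake"))
}

#' @rdname paper_fixture
#' @return \code{paper_pathway}: list with the chance-node tree
#'   (\code{root}), strategy definitions and setting profiles.
#' @export
paper_pathway <- function() {
  act <- function(items, component = NULL)
    list(type = "act", component = component, items = as.list(items))
  chance <- function(id, branches, component = NULL)
    list(type = "chance", id = id, component = component, branches = branches)
  br <- function(p, child = NULL) list(p = p, child = child)

  followup <- chance("q_followup", list(
    br("p_followup", act("q_phone")),
    br("~")))
  q_paper <- list(type = "seq", children = list(
    act(c("q_print", "q_post", "q_entry")), followup))

  consult_path <- function(which)
    chance(paste0("uptake_", which), list(
      br(paste0("p_attend_", which),
         act(c("organize_appt", "risk_pack", paste0("consult_", which)))),
      br("~")))

  root <- list(type = "seq", children = list(
    act(c("inv_print", "inv_staff", "inv_post"), component = "invitation"),
    chance("q_mode", list(br("p_paper", q_paper), br("~")),
           component = "questionnaire"),
    act("volpara", component = "volpara"),
    chance("vol_fail", list(br("p_fail", act("vol_followup")), br("~")),
           component = "volpara_implementation_issues"),
    chance("vol_birads", list(br("p_birads", act("birads_read")), br("~")),
           component = "volpara_implementation_issues"),
    act("aerial", component = "volpara_implementation_issues"),
    act(c("saliva_collection", "snp_staff", "snp_consumables"),
        component = "snp"),
    act(c("letter_retrieve", "letter_print", "letter_fill", "letter_post"),
        component = "risk_letter"),
    chance("risk_category", list(
      br("@p_high", consult_path("high")),
      br("@p_mod", consult_path("mod")),
      br("~")), component = "consultation")))

  base_components <- c("invitation", "questionnaire", "risk_letter",
                       "consultation")
  vbd_components <- c(base_components, "volpara",
                      "volpara_implementation_issues")
  list(
    stages = PATHWAY_STAGES,
    strategies = list(
      TC = list(components = base_components,
                risk_set = list("@p_high" = "p_high_tc", "@p_mod" = "p_mod_tc")),
      TC_VBD = list(components = vbd_components,
                    risk_set = list("@p_high" = "p_high_vbd", "@p_mod" = "p_mod_vbd")),
      TC_VBD_SNP = list(components = c(vbd_components, "snp"),
                        risk_set = list("@p_high" = "p_high_snp", "@p_mod" = "p_mod_snp"))),
    settings = list(
      trial = list(exclude_items = character(0),
                   exclude_components = character(0),
                   substitute = list()),
      nhs = list(
        exclude_items = c("inv_print", "inv_staff", "inv_post",
                          "letter_retrieve", "risk_pack"),
        exclude_components = "volpara_implementation_issues",
        substitute = list(consult_high = "consult_high_nhs",
                          consult_mod = "consult_mod_nhs"))),
    root = root)
}

#' @rdname paper_fixture
#' @return \code{paper_distributions}: data frame of uncertainty
#'   distribution specifications for the probabilistic sensitivity analysis
#'   (parameter_ref, target = "quantity" or "probability", family, p1..p4).
#'   Probabilities get moment-matched beta distributions at an effective
#'   sample size of 100; interview-elicited durations get uniform
#'   distributions over the elicited range (midpoint equal to the point
#'   value); tariff-like unit costs are left as point masses (no row).
#'   All rows are flagged \code{reconstructed}.
#' @export
paper_distributions <- function() {
  ess <- 100
  pp <- paper_probabilities()
  beta_rows <- data.frame(
    parameter_ref = pp$id, target = "probability", family = "beta",
    p1 = pp$value * ess, p2 = (1 - pp$value) * ess,
    p3 = NA_real_, p4 = NA_real_, stringsAsFactors = FALSE)
  u <- function(ref, lo, hi)
    data.frame(parameter_ref = ref, target = "quantity", family = "uniform",
               p1 = lo, p2 = hi, p3 = NA_real_, p4 = NA_real_,
               stringsAsFactors = FALSE)
  out <- rbind(beta_rows,
               u("inv_staff", 2, 8),
               u("q_entry", 12.5, 30),
               u("q_phone", 2.5, 7.5),
               u("vol_followup", 5, 7.5),
               u("letter_retrieve", 5, 10),
               u("organize_appt", 1.5, 3),
               u("risk_pack", 5, 30),
               u("saliva_collection", 2, 5))
  out$reconstructed <- TRUE
  out
}

#' @rdname paper_fixture
#' @return \code{paper_batch_schedule}: a \code{\link{batch_schedule}} for
#'   the 142-SNP genotyping test. The array chip (capacity 48, one control
#'   per batch, optimum 95 payable samples) and the staff-time anchors (2,165
#'   min for a single-sample batch; 38.39 min per slot at a full batch) are
#'   published; the box-level consumable detail is reconstructed and
#'   calibrated once so that the full-batch per-sample chips-plus-consumables
#'   share equals the published 51.73 GBP.
#' @export
paper_batch_schedule <- function() {
  staff <- solve_staff_anchors(time_single = 2165,
                               minutes_per_slot_full = 38.39,
                               slots_full = 96, slots_single = 2)
  batch_schedule(
    chip_capacity = 48,
    chip_cost = 1343.77,
    controls_per_batch = 1,
    max_batch = 95,
    staff_fixed_minutes = staff[["fixed"]],
    staff_minutes_per_slot = staff[["variable"]],
    staff_rate = 41,
    collection_cost_per_sample = time_cost(3.5, 41),
    consumables = data.frame(
      name = c("beadchip_reagent_kit", "prep_consumables"),
      box_cost = c(400, 59.45),
      box_size = c(48L, 4L),
      usage = c(1, 1),
      basis = "per_sample",
      reconstructed = TRUE,
      stringsAsFactors = FALSE))
}

#' @rdname paper_fixture
#' @return \code{paper_rollout_scenario}: national rollout scenario for the
#'   questionnaire + breast-density strategy: 240,000 first screens per year,
#'   full uptake, and the published per-woman strategy costs with and without
#'   the implementation issues observed in the trial.
#' @export
paper_rollout_scenario <- function() {
  list(id = "england_first_screens_2019_20",
       n_women_per_year = 240000,
       uptake = 1,
       per_woman_cost_perfect = 6.64,
       per_woman_cost_imperfect = 21.82,
       barrier_removal_fraction = 1,
       note = paste("Published per-woman costs of the questionnaire +",
                    "breast-density strategy (routine NHS delivery vs as",
                    "delivered in the trial); England first-screen volume,",
                    "2019-20 screening year"))
}

#' Write the packaged fixture bundle to a directory
#'
#' Emits \code{unit_costs.csv}, \code{resource_items.csv},
#' \code{probabilities.csv}, \code{pathway.json}, \code{distributions.csv},
#' \code{batch_schedule.json}, \code{rollout.json} and an identity
#' \code{inflation.json} (all unit costs are already at 2021 prices).
#'
#' @param dir Target directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
make_paper_fixture <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(x, f)
    utils::write.csv(x, file.path(dir, f), row.names = FALSE, quote = TRUE)
  wjson <- function(x, f)
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  wcsv(paper_unit_costs(), "unit_costs.csv")
  wcsv(paper_resource_items(), "resource_items.csv")
  wcsv(paper_probabilities(), "probabilities.csv")
  wcsv(paper_distributions(), "distributions.csv")
  wjson(paper_pathway(), "pathway.json")
  sched <- paper_batch_schedule()
  wjson(list(chip_capacity = sched$chip_capacity, chip_cost = sched$chip_cost,
             controls_per_batch = sched$controls_per_batch,
             max_batch = sched$max_batch,
             staff_fixed_minutes = sched$staff_fixed_minutes,
             staff_minutes_per_slot = sched$staff_minutes_per_slot,
             staff_rate = sched$staff_rate,
             collection_cost_per_sample = sched$collection_cost_per_sample,
             consumables = sched$consumables), "batch_schedule.json")
  wjson(paper_rollout_scenario(), "rollout.json")
  wjson(list("2021" = 100), "inflation.json")
  invisible(dir)
}

#' Locate the fixture bundle shipped with the package
#' @return Path to the installed fixture directory.
#' @export
paper_fixture_path <- function() {
  p <- system.file("extdata", "bcpredict", package = "stratcost")
  if (!nzchar(p)) stop("packaged fixture not found", call. = FALSE)
  p
}

#' Build the packaged pathway model
#'
#' Convenience wrapper: \code{build_model(paper_fixture_path())}.
#' @return A validated \code{pathway_model}.
#' @export
paper_model <- function() build_model(paper_fixture_path())
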