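#' Batch schedule for array genotyping
#'
#' Describes how the per-sample cost of the 142-SNP saliva test depends on
#' batch size: array chips of fixed capacity and cost, one non-payable
#' control sample per batch occupying a chip slot, consumables bought in
#' boxes of a set size, and staff time with a fixed per-batch component plus
#' a variable per-slot component.
#'
#' @param chip_capacity Samples (slots) per chip.
#' @param chip_cost Cost in GBP of one chip.
#' @param controls_per_batch Control samples per batch; controls occupy chip
#'   slots and consume per-sample consumables and staff time but are not
#'   payable samples.
#' @param max_batch Payable samples in the optimal (largest) batch.
#' @param staff_fixed_minutes Fixed staff minutes per batch.
#' @param staff_minutes_per_slot Variable staff minutes per occupied slot.
#' @param staff_rate Staff cost in GBP per hour.
#' @param collection_cost_per_sample Per-sample collection cost in GBP
#'   (charged per payable sample, independent of batching).
#' @param consumables Data frame with columns \code{name}, \code{box_cost},
#'   \code{box_size}, \code{usage} (units per sample-slot or per batch) and
#'   \code{basis} (\code{"per_sample"} or \code{"per_batch"}).
#' @return An object of class \code{batch_schedule}.
#' @export
batch_schedule <- function(chip_capacity, chip_cost, controls_per_batch,
                           max_batch, staff_fixed_minutes,
                           staff_minutes_per_slot, staff_rate,
                           collection_cost_per_sample = 0,
                           consumables = NULL) {
  if (chip_capacity < 1) stop("chip_capacity must be >= 1", call. = FALSE)
  for (f in c("chip_cost", "controls_per_batch", "staff_fixed_minutes",
              "staff_minutes_per_slot", "staff_rate",
              "collection_cost_per_sample"))
    check_nonnegative(get(f), f)
  if (is.null(consumables))
    consumables <- data.frame(name = character(0), box_cost = numeric(0),
                              box_size = integer(0), usage = numeric(0),
                              basis = character(0))
  if (any(consumables$box_size < 1))
    stop("consumable box_size must be >= 1", call. = FALSE)
  if (any(!consumables$basis %in% c("per_sample", "per_batch")))
    stop("consumable basis must be per_sample or per_batch", call. = FALSE)
  structure(list(chip_capacity = chip_capacity, chip_cost = chip_cost,
                 controls_per_batch = controls_per_batch,
                 max_batch = max_batch,
                 staff_fixed_minutes = staff_fixed_minutes,
                 staff_minutes_per_slot = staff_minutes_per_slot,
                 staff_rate = staff_rate,
                 collection_cost_per_sample = collection_cost_per_sample,
                 consumables = consumables),
            class = "batch_schedule")
}

#' Read a batch schedule from a JSON file
#' @param path Path to a JSON file in the fixture-bundle schema.
#' @return A \code{batch_schedule}.
#' @export
read_batch_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  batch_schedule(x$chip_capacity, x$chip_cost, x$controls_per_batch,
                 x$max_batch, x$staff_fixed_minutes,
                 x$staff_minutes_per_slot, x$staff_rate,
                 x$collection_cost_per_sample,
                 as.data.frame(x$consumables))
}

#' Calibrate the two-parameter staff-time model from printed anchors
#'
#' Staff time per batch is modelled as \code{fixed + variable * slots},
#' where slots = payable samples + controls. The two published anchors
#' (total minutes for a single-sample batch, and minutes per slot at the
#' full batch) determine the 2x2 linear system solved here.
#'
#' @param time_single Total staff minutes for a single-sample batch.
#' @param minutes_per_slot_full Staff minutes per slot at the full batch.
#' @param slots_full Occupied slots in the full batch (payable + controls).
#' @param slots_single Occupied slots in the single-sample batch.
#' @return Named vector \code{c(fixed =, variable =)} in minutes.
#' @export
solve_staff_anchors <- function(time_single, minutes_per_slot_full,
                                slots_full, slots_single) {
  total_full <- minutes_per_slot_full * slots_full
  variable <- (total_full - time_single) / (slots_full - slots_single)
  c(fixed = time_single - slots_single * variable, variable = variable)
}

slots_used <- function(batch_size, schedule)
  batch_size + schedule$controls_per_batch

#' Chips required for a batch
#'
#' @param batch_size Payable samples in the batch; >= 1.
#' @param schedule A \code{\link{batch_schedule}}.
#' @return \code{ceiling((batch_size + controls) / chip_capacity)}.
#' @export
chips_required <- function(batch_size, schedule) {
  if (any(batch_size < 1))
    stop("batch_size must be >= 1", call. = FALSE)
  ceiling(slots_used(batch_size, schedule) / schedule$chip_capacity)
}

#' Consumable cost of a batch
#'
#' Boxes cannot be bought fractionally: each consumable contributes
#' \code{box_cost * ceiling(total_usage / box_size)}, where per-sample usage
#' counts control samples.
#'
#' @inheritParams chips_required
#' @return Total consumable cost in GBP for the batch.
#' @export
consumable_cost <- function(batch_size, schedule) {
  if (any(batch_size < 1)) stop("batch_size must be >= 1", call. = FALSE)
  vapply(batch_size, function(b) {
    cons <- schedule$consumables
    if (!nrow(cons)) return(0)
    total_usage <- ifelse(cons$basis == "per_sample",
                          cons$usage * slots_used(b, schedule), cons$usage)
    sum(cons$box_cost * ceiling(total_usage / cons$box_size))
  }, numeric(1))
}

#' Staff time and cost of a batch
#'
#' @inheritParams chips_required
#' @return \code{staff_minutes}: total staff minutes,
#'   \code{fixed + variable * slots}; \code{staff_cost}: that time priced at
#'   the schedule's hourly rate.
#' @export
staff_minutes <- function(batch_size, schedule)
  schedule$staff_fixed_minutes +
    schedule$staff_minutes_per_slot * slots_used(batch_size, schedule)

#' @rdname staff_minutes
#' @export
staff_cost <- function(batch_size, schedule)
  time_cost(staff_minutes(batch_size, schedule), schedule$staff_rate)

#' Per-sample genotyping cost at a given batch size
#'
#' @inheritParams chips_required
#' @return One-row data frame (a batch-curve point): \code{batch_size},
#'   \code{chips_used}, \code{batch_total} (chips + consumables + staff +
#'   collection for the whole batch) and \code{per_sample_cost}
#'   (\code{batch_total / batch_size}).
#' @export
per_sample_cost <- function(batch_size, schedule) {
  if (any(batch_size < 1) || any(batch_size > schedule$max_batch))
    stop(sprintf("batch_size must be in [1, %d]", schedule$max_batch),
         call. = FALSE)
  chips <- chips_required(batch_size, schedule)
  total <- chips * schedule$chip_cost +
    consumable_cost(batch_size, schedule) +
    staff_cost(batch_size, schedule) +
    schedule$collection_cost_per_sample * batch_size
  data.frame(batch_size = batch_size, chips_used = chips,
             batch_total = total, per_sample_cost = total / batch_size)
}

#' The batch-size cost curve
#'
#' @param schedule A \code{\link{batch_schedule}}.
#' @param from,to Range of batch sizes (payable samples).
#' @return Data frame of batch-curve points, one row per batch size, of
#'   class \code{batch_curve}; plot with \code{plot()}.
#' @export
batch_curve <- function(schedule, from = 1, to = schedule$max_batch) {
  if (from < 1 || to > schedule$max_batch || from > to)
    stop(sprintf("range must lie within [1, %d]", schedule$max_batch),
         call. = FALSE)
  out <- per_sample_cost(seq.int(from, to), schedule)
  class(out) <- c("batch_curve", "data.frame")
  out
}

#' @export
plot.batch_curve <- function(x, ...) {
  plot(x$batch_size, x$per_sample_cost, type = "s",
       xlab = "Batch size (payable samples)",
       ylab = "Cost per sample (GBP)",
       main = "Genotyping cost per sample by batch size", ...)
  invisible(x)
}

#' Write a batch curve as CSV
#' @param curve A \code{batch_curve}.
#' @param path Output CSV path.
#' @param provenance Named character vector of comment headers.
#' @return Invisibly, the path.
#' @export
write_batch_curve <- function(curve, path, provenance = character(0)) {
  df <- data.frame(batch_size = curve$batch_size,
                   chips = curve$chips_used,
                   per_sample_cost = round_money(curve$per_sample_cost),
                   batch_total = round_money(curve$batch_total))
  write_report_csv(df, path, provenance)
}

#' Per-woman strategy cost as a function of genotyping batch size
#'
#' Combines the pathway model (all non-genotyping stages plus collection)
#' with the batch schedule's per-sample genotyping cost, replacing the
#' full-batch SNP-stage items of the fixture by the batch-size-dependent
#' cost. Reproduces the published scenario analysis.
#'
#' @param model A \code{pathway_model} whose SNP stage items are the
#'   full-batch per-sample shares.
#' @param schedule A \code{\link{batch_schedule}}.
#' @param strategy,setting Strategy and setting ids.
#' @param batch_sizes Vector of batch sizes.
#' @return Data frame with \code{batch_size}, \code{snp_per_sample} and
#'   \code{strategy_cost} (per woman).
#' @export
strategy_cost_by_batch <- function(model, schedule, strategy = "TC_VBD_SNP",
                                   setting = "nhs",
                                   batch_sizes = seq_len(schedule$max_batch)) {
  br <- evaluate_expected_cost(model, strategy, setting)
  snp_stage <- br$per_stage[["snp"]]
  base <- br$total - snp_stage
  pts <- per_sample_cost(batch_sizes, schedule)
  data.frame(batch_size = batch_sizes,
             snp_per_sample = pts$per_sample_cost,
             strategy_cost = base + pts$per_sample_cost)
}
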