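# Per-case orchestration (fit -> track -> kappa gate -> mirror -> lines ->
# classify -> sectors) and the cohort summary statistics.

#' Run the full pipeline on one case
#'
#' Fits the tensor field, tracks the pyramidal tract with the three-VOI
#' protocol for two simulated operators (the second operator's seed VOI is
#' dilated by one voxel), gates the case on voxel-wise Cohen's kappa, mirrors
#' right-sided cases to the left, builds the reference lines, classifies the
#' tumor, and measures the observed clock sector of the tract cross-section
#' on the Monro slice. Excluded cases carry `included = FALSE` and no sector
#' claims.
#'
#' @param case a `phantom_case` (from [make_phantom_case()] or
#'   [read_phantom_case()]).
#' @param params a [tracking_params()].
#' @param kappa_threshold operator-agreement exclusion threshold.
#' @param case_id identifier copied into the record.
#' @param verbose print per-stage log lines.
#' @return A one-row data.frame (`case_record`): `case_id`, `tumor_type`,
#'   `observed_sector`, `predicted_sector`, `match`, `kappa`, `included`,
#'   `reason`, plus the truth columns `true_type`/`true_sector` when the case
#'   carries ground truth.
#' @export
run_case <- function(case, params = tracking_params(), kappa_threshold = 0.7,
                     case_id = "case", verbose = FALSE) {
  t0 <- Sys.time()
  log_stage <- function(stage, note = "") {
    if (verbose)
      message(sprintf("[%s] %-10s %6.2fs %s", case_id, stage,
                      as.numeric(Sys.time() - t0, units = "secs"), note))
  }
  field <- fit_tensor_loglinear(case$dwi)
  log_stage("fit")
  tractA <- run_pt_protocol(field, case$vois, params)
  voisB <- voi_set(dilate_mask(case$vois$seed), case$vois$include_precentral,
                   case$vois$include_peduncle, case$vois$excludes)
  tractB <- run_pt_protocol(field, voisB, params)
  log_stage("track", paste0(length(tractA$streamlines), "/",
                            length(tractB$streamlines), " streamlines"))
  rec <- data.frame(case_id = case_id,
                    tumor_type = NA_character_,
                    observed_sector = NA_character_,
                    predicted_sector = NA_character_,
                    match = NA, kappa = NA_real_, included = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(case$truth)) {
    rec$true_type <- case$truth$true_type
    rec$true_sector <- case$truth$true_sector
  }
  if (length(tractA$streamlines) == 0 || length(tractB$streamlines) == 0) {
    rec$reason <- "tracking_failure"
    log_stage("gate", "no retained streamlines")
    return(rec)
  }
  maskA <- binarize_tract(tractA, case$grid, "tract_op_a")
  maskB <- binarize_tract(tractB, case$grid, "tract_op_b")
  agree <- cohen_kappa(maskA, maskB, tract_universe(maskA, maskB),
                       threshold = kappa_threshold)
  rec$kappa <- agree$kappa
  log_stage("gate", sprintf("kappa = %.3f (%s)", agree$kappa, agree$decision))
  if (agree$decision == "exclude") {
    rec$reason <- "kappa_below_threshold"
    return(rec)
  }
  # geometry: mirror right-sided cases to the left before classification
  pts <- do.call(rbind, tractA$streamlines)
  geom <- mirror_to_left(list(tumor_mask = case$tumor_mask,
                              extent_mask = case$extent_mask,
                              landmarks = case$landmarks, pt_points = pts),
                         case$midline_x)
  tract_m <- list(streamlines = list(geom$pt_points))
  lines <- build_reference_lines(geom$landmarks)
  k <- monro_axial_slice(geom$landmarks, case$grid)
  type <- classify_tumor(geom$tumor_mask, lines, k,
                         extent_mask = geom$extent_mask)
  cs <- cross_section(tract_m, k, case$grid)
  log_stage("classify", paste0("type ", type))
  rec$tumor_type <- as.character(type)
  rec$predicted_sector <- predict_sector(type)
  if (is.null(cs$centroid)) {
    rec$reason <- "no_tract_on_monro_slice"
    return(rec)
  }
  rec$observed_sector <- observed_sector(cs$centroid, geom$tumor_mask, k)
  rec$match <- rec$observed_sector == rec$predicted_sector
  rec$included <- TRUE
  rec$reason <- "ok"
  rec
}

# 6-connected one-voxel dilation of a volume_mask.
dilate_mask <- function(mask) {
  m <- mask$data
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  volume_mask(out, mask$label, mask$voxel_size_mm, mask$affine)
}

# Half-away-from-zero rounding (the usual printed style; R's round() is
# round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort summary: per-type counts, percentages, line-based aggregates
#'
#' Accepts either a vector of per-type counts (named by [tumor_types()], or
#' unnamed in that order) or a data.frame of case records (only included
#' records contribute). Percentages are `100 * count / total`, rounded
#' half-away-from-zero at `digits` decimals. The aggregates are:
#' lateral of line 1 = T3A + T3B + T5; medial of line 1 = T4A + T4B + T6;
#' anterior of line 2 = T2 + T5 + T6; beyond line 3 = T3A + T4A; between
#' lines 2 and 3 = T3B + T4B.
#'
#' @param x counts vector or records data.frame.
#' @param digits rounding for percentages (default 2; pass 1 to match
#'   one-decimal printed values).
#' @return list with `n`, `counts`, `percent`, `aggregates` (counts) and
#'   `aggregate_percent`, plus `concordance` (per-type sector concordance
#'   rate) when records are supplied.
#' @export
summarize_cohort <- function(x, digits = 2) {
  concordance <- NULL
  if (is.data.frame(x)) {
    inc <- x[x$included %in% TRUE, , drop = FALSE]
    if (nrow(inc) == 0) stop("empty cohort")
    counts <- table(factor(inc$tumor_type, levels = tumor_types()))
    concordance <- vapply(tumor_types(), function(tt) {
      sub <- inc[inc$tumor_type == tt, , drop = FALSE]
      if (nrow(sub) == 0) NA_real_ else mean(sub$match)
    }, 0)
    counts <- as.numeric(counts)
  } else {
    counts <- as.numeric(x)
    if (!is.null(names(x))) counts <- as.numeric(x[tumor_types()])
    if (length(counts) != 8 || any(is.na(counts)))
      stop("counts must cover the 8 tumor types")
  }
  if (sum(counts) == 0) stop("empty cohort")
  names(counts) <- tumor_types()
  n <- sum(counts)
  pct <- round_half_up(100 * counts / n, digits)
  agg <- c(lateral_of_line1 = sum(counts[c("T3A", "T3B", "T5")]),
           medial_of_line1 = sum(counts[c("T4A", "T4B", "T6")]),
           anterior_of_line2 = sum(counts[c("T2", "T5", "T6")]),
           beyond_line3 = sum(counts[c("T3A", "T4A")]),
           between_lines_2_3 = sum(counts[c("T3B", "T4B")]))
  out <- list(n = n, counts = counts, percent = pct, aggregates = agg,
              aggregate_percent = round_half_up(100 * agg / n, digits))
  if (!is.null(concordance)) out$concordance <- concordance
  out
}
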