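#' Phase means from an extracellular-flux trace
#'
#' Summarises a long-format instrument trace (one row per well, phase and
#' measurement cycle) into one value per well and phase: the mean of the
#' last `n_cycles` measurements of each phase (measurements stabilise
#' toward the end of an injection phase).
#'
#' @param trace `data.frame` with columns `well`, `phase`, `cycle`,
#'   `value`.
#' @param n_cycles Number of trailing cycles to average (default 3).
#' @return Wide `data.frame`: one row per well, one column per phase.
#' @export
phase_means <- function(trace, n_cycles = 3) {
  req <- c("well", "phase", "cycle", "value")
  miss <- setdiff(req, names(trace))
  if (length(miss)) stop("trace lacks column(s): ", paste(miss, collapse = ", "))
  if (any(trace$value < 0, na.rm = TRUE)) stop("phase measurements must be >= 0")
  sp <- split(trace, list(trace$well, trace$phase), drop = TRUE)
  means <- vapply(sp, function(d) {
    d <- d[order(d$cycle), ]
    mean(utils::tail(d$value, n_cycles))
  }, numeric(1))
  parts <- do.call(rbind, strsplit(names(means), ".", fixed = TRUE))
  out <- stats::reshape(
    data.frame(well = parts[, 1], phase = parts[, 2], value = unname(means),
               stringsAsFactors = FALSE),
    idvar = "well", timevar = "phase", direction = "wide")
  names(out) <- sub("^value\\.", "", names(out))
  rownames(out) <- NULL
  out
}

#' Mitochondrial stress test metrics from an OCR trace
#'
#' From phase-averaged oxygen consumption rates (basal, post-oligomycin,
#' post-FCCP, post-rotenone/antimycin A):
#' nonmitochondrial respiration = post_rotAA; basal mitochondrial
#' respiration = basal - nonmito; ATP-linked respiration =
#' basal - post_oligomycin; maximal respiration = post_FCCP - nonmito;
#' spare capacity = maximal - basal mitochondrial. All metrics are divided
#' by the per-well protein normalisation factor. Negative derived metrics
#' (e.g. post-oligomycin above basal) are flagged in `qc_flag`, never
#' clipped.
#'
#' @param trace Long-format OCR trace (see [phase_means()]) with phases
#'   `basal`, `post_oligomycin`, `post_FCCP`, `post_rotAA`.
#' @param protein Named numeric vector of per-well protein factors (> 0),
#'   or a single value; default 1 (no normalisation).
#' @param n_cycles Trailing cycles averaged per phase.
#' @return `data.frame` per well: `basal`, `nonmito`, `basal_mito`,
#'   `atp_linked`, `maximal`, `spare`, `qc_flag`.
#' @examples
#' tr <- expand.grid(well = "A1", cycle = 1:3,
#'                   phase = c("basal", "post_oligomycin", "post_FCCP", "post_rotAA"))
#' tr$value <- rep(c(100, 40, 150, 10), each = 3)
#' mito_stress_metrics(tr)  # atp_linked 60, maximal 140, spare 50
#' @export
mito_stress_metrics <- function(trace, protein = 1, n_cycles = 3) {
  ph <- phase_means(trace, n_cycles)
  need <- c("basal", "post_oligomycin", "post_FCCP", "post_rotAA")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("OCR trace missing phase(s): ", paste(miss, collapse = ", "))
  pf <- resolve_per_sample(protein, ph$well, "protein factor")
  if (any(pf <= 0)) stop("protein factor must be > 0")
  nonmito <- ph$post_rotAA
  basal_mito <- ph$basal - nonmito
  atp_linked <- ph$basal - ph$post_oligomycin
  maximal <- ph$post_FCCP - nonmito
  spare <- maximal - basal_mito
  out <- data.frame(
    well = ph$well,
    basal = ph$basal / pf, nonmito = nonmito / pf,
    basal_mito = basal_mito / pf, atp_linked = atp_linked / pf,
    maximal = maximal / pf, spare = spare / pf,
    stringsAsFactors = FALSE, row.names = NULL)
  out$qc_flag <- atp_linked < 0 | basal_mito < 0 | maximal < 0 | spare < 0 |
    nonmito > ph$basal
  out
}

#' Glycolytic rate test metrics from a PER trace
#'
#' From phase-averaged proton efflux rates (basal, post-rotenone/antimycin
#' A, post-2-deoxyglucose): basal glycolysis = basal PER; compensatory
#' glycolysis = post_rotAA - post_2DG (the PER after 2-DG subtracted from
#' the PER after rotenone/antimycin A); blocked = post_2DG. All
#' protein-normalised; negative derived metrics flagged, not clipped.
#'
#' @inheritParams mito_stress_metrics
#' @param trace Long-format PER trace with phases `basal`, `post_rotAA`,
#'   `post_2DG`.
#' @return `data.frame` per well: `basal_glycolysis`, `compensatory`,
#'   `blocked`, `qc_flag`.
#' @export
glycolytic_rate_metrics <- function(trace, protein = 1, n_cycles = 3) {
  ph <- phase_means(trace, n_cycles)
  need <- c("basal", "post_rotAA", "post_2DG")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("PER trace missing phase(s): ", paste(miss, collapse = ", "))
  pf <- resolve_per_sample(protein, ph$well, "protein factor")
  if (any(pf <= 0)) stop("protein factor must be > 0")
  compensatory <- ph$post_rotAA - ph$post_2DG
  out <- data.frame(
    well = ph$well,
    basal_glycolysis = ph$basal / pf,
    compensatory = compensatory / pf,
    blocked = ph$post_2DG / pf,
    stringsAsFactors = FALSE, row.names = NULL)
  out$qc_flag <- compensatory < 0
  out
}
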