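# Developmental epigenetic signature classification.
#
# The five labels mirror the gene groups a two-mark developmental time course
# distinguishes: NO_MARK (neither mark ever accumulates), ROD_SPECIFIC
# (de novo activating-mark gain late in development with no repressive mark at
# any stage), NONROD_RETINAL (high repressive mark throughout with a lower but
# distinct activating mark), UBIQUITOUS (strong activating mark at every
# stage, no repressive mark) and OTHER.

SIGNATURE_LABELS <- c("NO_MARK", "ROD_SPECIFIC", "NONROD_RETINAL",
                      "UBIQUITOUS", "OTHER")

#' Classification thresholds
#'
#' All thresholds are multiples of the mock-control background occupancy `b`:
#' `c_rep` is the ceiling under which a mark counts as absent, `c_act` the
#' floor above which it counts as strongly present, and `f_min` the minimum
#' late/early fold for a de novo gain. Given Poisson counting noise on
#' TSS-window counts (coefficient of variation ~1/sqrt(count)), `c_rep` must
#' sit several standard deviations above background; 2.5 keeps the
#' false-absence rate per condition below 1e-4 for window counts of order 10.
#'
#' @param c_rep Absence ceiling (x background).
#' @param c_act Presence floor (x background).
#' @param f_min De novo fold floor.
#' @return List of class `signature_thresholds`.
#' @export
signature_thresholds <- function(c_rep = 2.5, c_act = 3, f_min = 3) {
  if (any(c(c_rep, c_act, f_min) <= 0)) stop("thresholds must be positive")
  structure(list(c_rep = c_rep, c_act = c_act, f_min = f_min),
            class = "signature_thresholds")
}

# Column getter: occupancies of one mark at one stage.
mark_cols <- function(mat, mark, stages = STAGES) {
  mat[, sample_key(mark, stages), drop = FALSE]
}

#' Screen for the rod-specific de novo signature
#'
#' A gene carries the signature when, around its TSS, (i) the repressive mark
#' (H3K27me3) stays below `c_rep * b` at every stage, (ii) the activating mark
#' (H3K4me2) is also below `c_rep * b` at the two early stages, and (iii) at
#' the final stage the activating mark reaches at least `c_act * b` and at
#' least `f_min` times the larger of its earliest-stage value and `b`.
#' With `use_body = TRUE` condition (ii)-(iii) must additionally hold on the
#' gene-body occupancy matrix (the full rod signature covers the whole gene).
#'
#' @param tss_mat TSS +/- flank occupancy matrix (mark:stage columns).
#' @param b Mock-control background occupancy.
#' @param body_mat Gene-body occupancy matrix (required for `use_body`).
#' @param thresholds A [signature_thresholds()].
#' @param use_body Also require the de novo gain over the gene body.
#' @param stages Stage order, earliest to latest.
#' @return Named logical vector.
#' @export
rod_signature_screen <- function(tss_mat, b, body_mat = NULL,
                                 thresholds = signature_thresholds(),
                                 use_body = FALSE, stages = STAGES) {
  th <- thresholds
  denovo <- function(mat) {
    k4 <- mark_cols(mat, "H3K4me2", stages)
    early <- k4[, 1:2, drop = FALSE]
    last <- k4[, length(stages)]
    first <- k4[, 1]
    (apply(early, 1, max) < th$c_rep * b) &
      (last >= th$c_act * b) &
      (last >= th$f_min * pmax(first, b))
  }
  k27 <- mark_cols(tss_mat, "H3K27me3", stages)
  flag <- (apply(k27, 1, max) < th$c_rep * b) & denovo(tss_mat)
  if (use_body) {
    if (is.null(body_mat)) stop("body_mat required when use_body = TRUE")
    flag <- flag & denovo(body_mat)
  }
  stats::setNames(flag, rownames(tss_mat))
}

#' Classify genes into epigenetic signature classes
#'
#' Applies the label rules in fixed precedence (`NO_MARK` > `ROD_SPECIFIC` >
#' `NONROD_RETINAL` > `UBIQUITOUS` > `OTHER`) so every gene receives exactly
#' one label:
#'
#' * `NO_MARK`: Euclidean row norm below [no_mark_cutoff()].
#' * `ROD_SPECIFIC`: [rod_signature_screen()].
#' * `NONROD_RETINAL`: repressive mark at least `c_act * b` at every stage,
#'   with a lower but distinct activating mark (stage-mean H3K4me2 in
#'   `[b, c_act * b)`). Stage means are used for the level band because
#'   per-stage Poisson noise would otherwise dominate the call.
#' * `UBIQUITOUS`: stage-mean activating mark at least `c_act * b` with the
#'   repressive mark below `c_rep * b` at every stage.
#'
#' @inheritParams rod_signature_screen
#' @param cutoff No-mark cutoff; defaults to `no_mark_cutoff(b, ncol(tss_mat))`.
#' @return data.frame with columns gene, label (factor with the five labels)
#'   and the per-rule logical evidence columns.
#' @export
classify_signatures <- function(tss_mat, b, body_mat = NULL,
                                thresholds = signature_thresholds(),
                                use_body = FALSE, stages = STAGES,
                                cutoff = NULL) {
  th <- thresholds
  cutoff <- cutoff %||% no_mark_cutoff(b, ncol(tss_mat))
  no_mark <- classify_no_mark(tss_mat, cutoff)
  rod <- rod_signature_screen(tss_mat, b, body_mat, th, use_body, stages)
  k4 <- mark_cols(tss_mat, "H3K4me2", stages)
  k27 <- mark_cols(tss_mat, "H3K27me3", stages)
  k4_mean <- rowMeans(k4)
  k27_min <- apply(k27, 1, min)
  k27_max <- apply(k27, 1, max)
  nonrod <- (k27_min >= th$c_act * b) &
    (k4_mean >= b) & (k4_mean < th$c_act * b)
  ubiq <- (k4_mean >= th$c_act * b) & (k27_max < th$c_rep * b)
  label <- rep("OTHER", nrow(tss_mat))
  label[ubiq] <- "UBIQUITOUS"
  label[nonrod] <- "NONROD_RETINAL"
  label[rod] <- "ROD_SPECIFIC"
  label[no_mark] <- "NO_MARK"
  data.frame(gene = rownames(tss_mat),
             label = factor(label, levels = SIGNATURE_LABELS),
             no_mark = no_mark, rod = rod, nonrod = nonrod, ubiquitous = ubiq,
             row.names = NULL, stringsAsFactors = FALSE)
}
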