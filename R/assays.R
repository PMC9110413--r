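#' Percent calcium influx of one vesicle
#'
#' `100 * (F_sample - F_background) / (F_ionomycin - F_background)`:
#' influx normalized to the maximum influx driven by the ionophore
#' ionomycin. Vesicles with `F_ionomycin <= F_background` are unusable and
#' return NA with a reason. Noise can push values outside `[0, 100]`; such
#' values are reported raw with `out_of_range = TRUE`, never clipped.
#' The formula is invariant to affine rescaling (gain and offset) applied
#' uniformly to the three measurements.
#'
#' @param f_background,f_sample,f_ionomycin Vesicle mean fluorescence in
#'   the three acquisition phases (vectorized).
#' @return Data frame: percent, out_of_range, excluded, reason.
#' @export
calcium_influx <- function(f_background, f_sample, f_ionomycin) {
  n <- max(length(f_background), length(f_sample), length(f_ionomycin))
  f_background <- rep_len(f_background, n)
  f_sample <- rep_len(f_sample, n)
  f_ionomycin <- rep_len(f_ionomycin, n)
  usable <- f_ionomycin > f_background
  pct <- ifelse(usable,
                100 * (f_sample - f_background) / (f_ionomycin - f_background),
                NA_real_)
  data.frame(percent = pct,
             out_of_range = !is.na(pct) & (pct < 0 | pct > 100),
             excluded = !usable,
             reason = ifelse(usable, "", "F_ionomycin <= F_background"))
}

#' Field-averaged calcium influx
#'
#' Arithmetic mean of per-vesicle influx percents over the usable vesicles
#' in one field of view.
#'
#' @param influx Output of [calcium_influx()], or a numeric vector of
#'   percents.
#' @return Mean percent.
#' @export
field_average_influx <- function(influx) {
  pct <- if (is.data.frame(influx)) influx$percent[!influx$excluded]
  else influx
  if (length(pct) == 0 || all(is.na(pct))) stop("zero usable vesicles")
  mean(pct, na.rm = TRUE)
}

#' Percent LDH cytotoxicity
#'
#' Each well's LDH signal is the 490 nm absorbance minus the 680 nm
#' background absorbance; cytotoxicity is the sample signal normalized
#' between the spontaneous-release and maximum-lysis controls:
#' `100 * (LDH_sample - LDH_spontaneous) / (LDH_maximum - LDH_spontaneous)`.
#'
#' @param a490_sample,a680_sample Sample absorbances.
#' @param a490_spontaneous,a680_spontaneous Spontaneous (no treatment)
#'   control absorbances.
#' @param a490_maximum,a680_maximum Maximum-lysis control absorbances.
#' @return Percent cytotoxicity (vectorized over samples).
#' @export
ldh_cytotoxicity <- function(a490_sample, a680_sample,
                             a490_spontaneous, a680_spontaneous,
                             a490_maximum, a680_maximum) {
  s <- a490_sample - a680_sample
  sp <- a490_spontaneous - a680_spontaneous
  mx <- a490_maximum - a680_maximum
  if (any(mx - sp <= 0)) stop("corrected maximum must exceed spontaneous")
  100 * (s - sp) / (mx - sp)
}

#' Relative gene expression from qPCR Ct values
#'
#' Per sample, dCt = Ct(gene) - mean Ct over the housekeeping genes;
#' ddCt = dCt - mean dCt of the reference group for that gene; fold change
#' = 2^(-ddCt) (amplification efficiency 2, recorded in the output). By
#' construction the reference group's fold changes average to 1 on the
#' log2 scale.
#'
#' @param ct Data frame with columns `sample`, `group`, `gene`, `ct`.
#' @param housekeeping Character vector of housekeeping gene names (e.g.
#'   GAPDH and 18S rRNA); every sample must have all of them measured.
#' @param reference_group Reference (buffer control) group name, default
#'   `"PBS"`.
#' @return Data frame: sample, group, gene, dct, ddct, fold_change; with
#'   attribute `"efficiency_base" = 2`.
#' @export
relative_expression <- function(ct, housekeeping,
                                reference_group = "PBS") {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct)),
            all(is.finite(ct$ct)))
  if (!reference_group %in% ct$group) stop("empty reference group")
  hk_mean <- sapply(split(ct, ct$sample), function(d) {
    hk <- d$ct[d$gene %in% housekeeping]
    if (length(unique(d$gene[d$gene %in% housekeeping])) < length(housekeeping))
      stop("missing housekeeping measurement for sample ", d$sample[1])
    mean(hk)
  })
  goi <- ct[!ct$gene %in% housekeeping, , drop = FALSE]
  goi$dct <- as.numeric(goi$ct - hk_mean[as.character(goi$sample)])
  ref_mean <- tapply(goi$dct[goi$group == reference_group],
                     goi$gene[goi$group == reference_group], mean)
  if (any(!unique(goi$gene) %in% names(ref_mean)))
    stop("reference group missing for some gene(s)")
  goi$ddct <- as.numeric(goi$dct - ref_mean[as.character(goi$gene)])
  goi$fold_change <- 2^(-goi$ddct)
  rownames(goi) <- NULL
  out <- goi[, c("sample", "group", "gene", "dct", "ddct", "fold_change")]
  attr(out, "efficiency_base") <- 2
  out
}
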