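#' Band-to-control fluorescence intensity ratio
#'
#' Ratio of mean fluorescence inside a chromosomal band ROI to that of a
#' control ROI on the same chromosome.
#'
#' @param image Intensity matrix.
#' @param band_roi,control_roi Logical matrices (or linear index vectors)
#'   selecting the two non-empty regions.
#' @return Scalar ratio.
#' @export
band_ratio <- function(image, band_roi, control_roi) {
  pick <- function(roi, what) {
    v <- if (is.logical(roi)) image[roi] else image[as.integer(roi)]
    if (!length(v)) stopf("%s ROI is empty", what)
    v
  }
  band <- pick(band_roi, "band")
  ctrl <- pick(control_roi, "control")
  if (mean(ctrl) <= 0) stopf("control region mean must be > 0")
  mean(band) / mean(ctrl)
}

# Length-axis profile of a rectangular ROI: average across the width
# (rows), one value per length sample (columns), resampled to n_out.
roi_profile <- function(img, n_out = 101) {
  p <- colMeans(img)
  if (length(p) == n_out) return(p)
  approx(seq_along(p), p, xout = seq(1, length(p), length.out = n_out))$y
}

#' Locus-aligned enrichment profiles across nuclei
#'
#' For each nucleus, computes the fluorescence profile along a fixed
#' rectangular ROI spanning the locus (averaged across the ROI width),
#' min-max normalizes it to \[0, 1\], and circularly shifts both channels
#' so the maximum of the locus-tag channel sits at the central sample.
#' Profiles are resampled to a common length so replicates average
#' cleanly; the replicate mean and SEM are returned.
#'
#' @param signal_rois,tag_rois Lists (one element per nucleus) of
#'   rectangular ROI matrices: rows = width, columns = length axis.
#' @param n_samples Common profile length (odd; default 101).
#' @return List with `profiles` (tibble: `nucleus`, `position` 0-1,
#'   `signal`, `tag`), `mean_profile` (tibble: `position`, `signal_mean`,
#'   `signal_sem`, `tag_mean`, `tag_sem`), and `excluded` (indices of
#'   nuclei with a flat tag or signal channel).
#' @export
locus_profile <- function(signal_rois, tag_rois, n_samples = 101) {
  stopifnot(length(signal_rois) == length(tag_rois))
  if (n_samples %% 2 == 0) stopf("n_samples must be odd")
  mid <- (n_samples + 1) / 2
  excluded <- integer(0)
  rows <- list()
  for (i in seq_along(signal_rois)) {
    sig <- roi_profile(signal_rois[[i]], n_samples)
    tag <- roi_profile(tag_rois[[i]], n_samples)
    if (diff(range(tag)) == 0 || diff(range(sig)) == 0) {
      excluded <- c(excluded, i)
      inform(sprintf("nucleus %d excluded: flat channel", i))
      next
    }
    norm <- function(v) (v - min(v)) / (max(v) - min(v))
    sig <- norm(sig); tag <- norm(tag)
    shift <- mid - which.max(tag)
    rot <- function(v, k) if (k %% n_samples == 0) v else
      c(tail(v, -((-k) %% n_samples)), head(v, (-k) %% n_samples))
    rows[[length(rows) + 1]] <- tibble(
      nucleus = i, position = seq(0, 1, length.out = n_samples),
      signal = rot(sig, shift), tag = rot(tag, shift))
  }
  if (!length(rows)) stopf("no usable nuclei")
  profiles <- bind_rows(rows)
  mean_profile <- profiles %>%
    group_by(.data$position) %>%
    summarise(signal_mean = mean(.data$signal),
              signal_sem = sd(.data$signal) / sqrt(n()),
              tag_mean = mean(.data$tag),
              tag_sem = sd(.data$tag) / sqrt(n()), .groups = "drop")
  list(profiles = profiles, mean_profile = mean_profile,
       excluded = excluded)
}

#' ATAC-qPCR fold enrichment of open chromatin
#'
#' `2 ^ [(Cp_test,naked - Cp_test,ATAC) - (Cp_neg,naked - Cp_neg,ATAC)]`:
#' accessibility of a test region in tagmented (ATAC) versus genomic
#' ("naked") DNA, referenced to a closed-chromatin negative control
#' region.
#'
#' @param cp Data frame with columns `region`, `template` (values
#'   `"naked"` and `"ATAC"`), and `cp`.
#' @param test_region,negative_region Region names present in `cp`.
#' @return Scalar fold enrichment.
#' @export
atac_fold_enrichment <- function(cp, test_region, negative_region) {
  cp <- as_tibble(cp)
  get <- function(region, template) {
    v <- cp$cp[cp$region == region & cp$template == template]
    if (length(v) != 1 || !is.finite(v))
      stopf("missing or non-unique Cp for region '%s', template '%s'",
            region, template)
    v
  }
  d_test <- get(test_region, "naked") - get(test_region, "ATAC")
  d_neg <- get(negative_region, "naked") - get(negative_region, "ATAC")
  2^(d_test - d_neg)
}

#' Reference-normalized relative expression (delta-delta-Ct)
#'
#' `2 ^ -[(Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator]`,
#' assuming an amplification efficiency of 2 per cycle.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator The same in the
#'   calibrator condition.
#' @return Fold change relative to the calibrator.
#' @export
relative_expression <- function(ct_target_sample, ct_ref_sample,
                                ct_target_calibrator, ct_ref_calibrator) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
            ct_ref_calibrator)
  if (any(!is.finite(vals))) stopf("all four Ct values must be finite")
  2^-((ct_target_sample - ct_ref_sample) -
        (ct_target_calibrator - ct_ref_calibrator))
}
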