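# Corrected total fluorescence (CTF) quantification.

#' Corrected total fluorescence of an ROI
#'
#' `CTF = integrated intensity - ROI area x mean background fluorescence`,
#' with the integrated intensity summed over the ROI mask and the background
#' mean taken over a user-supplied background-only mask ("ROI" in the
#' formula is the ROI *area*, the standard corrected-total-fluorescence
#' convention). Adding a constant offset to the whole image cancels exactly;
#' a multiplicative gain scales CTF linearly.
#'
#' @param image 2D intensity matrix.
#' @param roi_mask,background_mask logical matrices the same size as
#'   `image`; both non-empty and disjoint.
#' @return object of class `roi_fluorescence`: `integrated_intensity`,
#'   `roi_area_px`, `background_mean`, `ctf`.
#' @export
compute_ctf <- function(image, roi_mask, background_mask) {
  vf_check(is.matrix(image) && all(is.finite(image)),
           "vascflow_parameter_error", "image must be a finite matrix")
  for (nm in c("roi_mask", "background_mask")) {
    m <- get(nm)
    vf_check(is.logical(m) && all(dim(m) == dim(image)),
             "vascflow_mask_error",
             sprintf("%s must be a logical matrix matching the image", nm))
    vf_check(any(m), "vascflow_mask_error", sprintf("%s is empty", nm))
  }
  vf_check(!any(roi_mask & background_mask), "vascflow_mask_error",
           "ROI and background masks overlap")
  integrated <- sum(image[roi_mask])
  area <- sum(roi_mask)
  bg <- mean(image[background_mask])
  structure(list(integrated_intensity = integrated, roi_area_px = area,
                 background_mean = bg, ctf = integrated - area * bg),
            class = "roi_fluorescence")
}

#' Normalize CTF values to the mean of a control group
#'
#' @param ctf numeric vector of sample CTF values (or `roi_fluorescence`
#'   objects).
#' @param control numeric vector of control CTF values (mean must be
#'   nonzero).
#' @return `ctf / mean(control)`.
#' @export
normalize_ctf <- function(ctf, control) {
  as_num <- function(x) {
    if (is.list(x)) vapply(x, function(e) e$ctf, 0) else x
  }
  ctf <- as_num(ctf); control <- as_num(control)
  check_finite_vector(ctf, "ctf")
  check_finite_vector(control, "control")
  vf_check(mean(control) != 0, "vascflow_parameter_error",
           "control CTF mean is zero")
  ctf / mean(control)
}
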