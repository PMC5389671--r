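#' Mirror-template quadruple at a candidate point
#'
#' Cuts an `n` x `n` region of interest centered on the integer candidate
#' `(x, y)` and builds four reconstructed particle templates: the ROI is
#' split vertically at the candidate column, each half is mirrored and
#' concatenated back onto itself, giving `T_L` (left half + its mirror) and
#' `T_R` (mirror + right half); splitting horizontally at the candidate row
#' gives `T_T` and `T_B`.  `n` must be odd and the shared central column/row
#' belongs to both halves, so each template is exactly `n` x `n` and exactly
#' mirror-symmetric about its central column (`T_L`, `T_R`) or row
#' (`T_T`, `T_B`).  If the true particle center lies at `(x, y)`, all four
#' templates reconstruct the same particle.
#'
#' @param image a numeric matrix (rows = y, columns = x) or `scene_image`.
#' @param x,y integer candidate center (column, row).
#' @param n odd template side length in pixels; the ROI must fit inside the
#'   image.
#' @return an object of class `template_quad`: a list with matrices `T_L`,
#'   `T_R`, `T_T`, `T_B`, the side `n` and the `origin` `(x, y)`.
#' @export
extract_templates <- function(image, x, y, n) {
  px <- scene_pixels(image)
  n <- as.integer(n)
  if (n < 3L || n %% 2L == 0L)
    stop("template side `n` must be an odd integer >= 3", call. = FALSE)
  x <- as.integer(x); y <- as.integer(y)
  h <- (n - 1L) %/% 2L
  if (x - h < 1L || x + h > ncol(px) || y - h < 1L || y + h > nrow(px))
    stop("ROI of side ", n, " at (", x, ", ", y, ") exits the image",
         call. = FALSE)
  roi <- px[(y - h):(y + h), (x - h):(x + h), drop = FALSE]
  mid <- h + 1L
  left  <- roi[, 1:mid, drop = FALSE]
  right <- roi[, mid:n, drop = FALSE]
  top   <- roi[1:mid, , drop = FALSE]
  bottom <- roi[mid:n, , drop = FALSE]
  structure(
    list(T_L = cbind(left,  left[, (mid - 1L):1, drop = FALSE]),
         T_R = cbind(right[, mid:2, drop = FALSE], right),
         T_T = rbind(top,   top[(mid - 1L):1, , drop = FALSE]),
         T_B = rbind(bottom[mid:2, , drop = FALSE], bottom),
         n = n, origin = c(x = x, y = y)),
    class = "template_quad")
}

# Sample Pearson correlation between two equally sized templates; a
# zero-variance template yields 0 (flagged upstream), never NaN.
template_correlation <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  cor(as.vector(a), as.vector(b))
}
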