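# Hair detection and inpainting.
#
# Hairs are thin dark curvilinear structures: a morphological black-hat
# (grayscale closing minus image) of the luminance channel with a bank of
# oriented linear structuring elements responds strongly along them and
# weakly elsewhere.  The maximum response over orientations is thresholded
# into a hair mask, which is then dilated by one pixel to cover
# anti-aliased stroke edges.  Inpainting replaces hair pixels by iterative
# 3 x 3 neighborhood averaging over non-hair (or already filled) pixels
# until convergence, so filled values are convex combinations of the
# surrounding intact pixels.

#' Detect and remove hair strokes from a dermoscopy image
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`.
#' @param se_length Length of the oriented linear structuring elements.
#' @param angles Orientations (degrees) of the element bank.
#' @param threshold Black-hat response threshold for hair pixels.
#' @param min_length Minimum bounding-box diagonal of a detected
#'   component; shorter (blob-like) candidates are discarded.
#' @param min_elongation Minimum `diagonal^2 / area` of a component;
#'   compact candidates are discarded.
#' @param max_halfwidth Maximum local half-width (distance-map value) of
#'   a candidate pixel; wider response plateaus are not hair.
#' @return List of class `hair_artifacts` with `hair_mask` (0/1 matrix)
#'   and `inpainted` (RGB array); non-hair pixels are unchanged.
#' @export
remove_hair <- function(img, se_length = 5L, angles = seq(0, 165, by = 22.5),
                        threshold = 0.08, min_length = 25, min_elongation = 2,
                        max_halfwidth = 3) {
  stopifnot(length(dim(img)) == 3L)
  gray <- luminance(img)
  response <- matrix(0, nrow(gray), ncol(gray))
  line_brush <- function(len, angle) {
    a <- angle %% 180
    if (a <= 90) return(EBImage::makeBrush(len, shape = "line", angle = a))
    b <- EBImage::makeBrush(len, shape = "line", angle = 180 - a)
    b[rev(seq_len(nrow(b))), , drop = FALSE]  # mirror into (90, 180)
  }
  for (ang in angles) {
    se <- line_brush(se_length, ang)
    closed <- EBImage::closing(gray, se)
    response <- pmax(response, closed - gray)
  }
  cand <- response > threshold
  # hairs are locally thin: prune response plateaus wider than a stroke
  if (any(cand)) {
    dm <- EBImage::distmap(cand + 0)
    cand <- cand & dm <= max_halfwidth
  }
  # hairs are long, curvilinear components; variegation blobs and border
  # lobes are short or compact.  Keep components by extent and elongation.
  if (any(cand)) {
    lab <- EBImage::bwlabel(cand + 0)
    keep <- logical(max(lab))
    for (k in seq_len(max(lab))) {
      px <- which(lab == k, arr.ind = TRUE)
      diag_len <- sqrt(diff(range(px[, 1]))^2 + diff(range(px[, 2]))^2)
      keep[k] <- diag_len >= min_length && diag_len^2 / nrow(px) >= min_elongation
    }
    cand <- matrix(lab > 0 & keep[pmax(lab, 1)], nrow(gray), ncol(gray))
  }
  hair <- cand
  if (any(hair)) {
    hair <- EBImage::dilate(hair + 0, EBImage::makeBrush(3, "box")) > 0
  }
  inpainted <- img
  if (any(hair)) {
    for (ch in 1:3) {
      inpainted[, , ch] <- inpaint_channel(img[, , ch], hair)
    }
  }
  structure(list(hair_mask = matrix(as.integer(hair), nrow(gray), ncol(gray)),
                 inpainted = inpainted),
            class = "hair_artifacts")
}

# Iterative neighborhood averaging: unknown pixels take the mean of their
# known 3 x 3 neighbors; repeat until all pixels are filled and the filled
# values stabilize.
inpaint_channel <- function(ch, unknown, tol = 1e-4, max_iters = 500L) {
  H <- nrow(ch); W <- ncol(ch)
  known <- !unknown
  val <- ch
  val[unknown] <- 0
  wts <- known + 0
  shift_sum <- function(m) {
    out <- matrix(0, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rs <- clamp(seq_len(H) + dr, 1L, H)
      cs <- clamp(seq_len(W) + dc, 1L, W)
      out <- out + m[rs, cs]
    }
    out
  }
  filled <- known
  for (it in seq_len(max_iters)) {
    num <- shift_sum(val * (filled + 0))
    den <- shift_sum(filled + 0)
    upd <- unknown & den > 0
    if (!any(upd)) break
    new_val <- val
    new_val[upd] <- num[upd] / den[upd]
    delta <- max(abs(new_val[upd] - val[upd]))
    newly <- upd & !filled
    val <- new_val
    filled <- filled | upd
    if (!any(unknown & !filled) && delta < tol) break
  }
  out <- ch
  out[unknown] <- val[unknown]
  out
}
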