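# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every generator routes its randomness through this, making outputs pure
# functions of (params, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Replicate-pad a matrix by `p` pixels on every side.
pad_replicate <- function(m, p) {
  m[c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p)),
    c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p)), drop = FALSE]
}

# Convolve with a normalized brush using replicate padding (filter2 itself is
# circular; padding by the brush radius removes the wrap-around).
filter_padded <- function(img, brush) {
  p <- (max(dim(brush)) - 1L) %/% 2L + 1L
  pad <- pad_replicate(img, p)
  out <- EBImage::filter2(pad, brush)
  out[(p + 1L):(p + nrow(img)), (p + 1L):(p + ncol(img)), drop = FALSE]
}

#' Gaussian blur with replicate boundary handling
#'
#' @param img numeric matrix.
#' @param sigma standard deviation of the Gaussian kernel, in pixels.
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  br <- EBImage::makeBrush(k, shape = "Gaussian", sigma = sigma)
  filter_padded(img, br)
}

# Local (moving-window) mean with a square window of odd side `w` pixels.
local_mean <- function(img, w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  br <- matrix(1 / (w * w), w, w)
  filter_padded(img, br)
}

# Local mean over a disc of radius `r_px`; used for background-circle search.
disc_mean <- function(img, r_px) {
  d <- 2L * as.integer(ceiling(r_px)) + 1L
  br <- EBImage::makeBrush(d, shape = "disc")
  br <- br / sum(br)
  filter_padded(img, br)
}

# Bilinear interpolation at continuous pixel coordinates (1-based, pixel
# centers at integers). Points outside the frame return NA.
interp_bilinear <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(pmax(floor(x), 1L), nx - 1L)
  y0 <- pmin(pmax(floor(y), 1L), ny - 1L)
  fx <- x - x0; fy <- y - y0
  v <- img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    img[cbind(x0 + 1L, y0 + 1L)] * fx * fy
  out[ok] <- v
  out
}

# 8-connected component labelling of a logical matrix. Returns an integer
# matrix of labels (0 = background). EBImage::bwlabel is 4-connected, hence
# this implementation on top of igraph components.
label8 <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  out <- matrix(0L, nrow(mask), ncol(mask))
  lin <- which(mask)
  if (!length(lin)) return(out)
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- arrayInd(lin, dim(mask))
  from <- integer(0); to <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    ni <- pos[, 1L] + d[1L]; nj <- pos[, 2L] + d[2L]
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    nlin <- (nj[ok] - 1L) * nr + ni[ok]
    m <- match(nlin, lin)
    sel <- !is.na(m)
    from <- c(from, which(ok)[sel]); to <- c(to, m[sel])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(lin),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  out[lin] <- as.integer(comp)
  out
}

# Trapezoidal integral of y(t).
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((t[-1L] - t[-n]) * (y[-1L] + y[-n]) / 2)
}

# Running median over a centered window of `k` samples (k made odd).
running_median <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < 3L) return(x)
  k <- min(k, if (length(x) %% 2L == 1L) length(x) else length(x) - 1L)
  stats::runmed(x, k, endrule = "median")
}

# Running mean over a centered window of `k` samples (edges shrink).
running_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- k %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
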