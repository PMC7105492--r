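# Independent brute-force oracles used across the suite.

# Sholl oracle: 8-connected components of mask-intersected ring pixels
# (graph components via igraph, independent of the angular-walk counter).
sholl_oracle <- function(mask, center_um, r_um,
                         px = attr(mask, "pixel_size_um")) {
  cpx <- center_um / px + 0.5
  ring <- astrocr:::circle_ring_pixels(dim(mask), cpx, r_um / px)
  if (is.null(ring)) return(NA_integer_)
  sel <- ring[mask[ring], , drop = FALSE]
  if (!nrow(sel)) return(0L)
  adj <- which(outer(sel[, 1], sel[, 1], function(a, b) abs(a - b) <= 1) &
                 outer(sel[, 2], sel[, 2], function(a, b) abs(a - b) <= 1),
               arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  igraph::components(g)$no
}

# Diameter oracle: O(n^2) over all pixel pairs.
diameter_oracle <- function(pixels, px = 1) {
  n <- nrow(pixels)
  if (n < 2) return(0)
  d2 <- outer(pixels[, 1], pixels[, 1], "-")^2 +
    outer(pixels[, 2], pixels[, 2], "-")^2
  sqrt(max(d2)) * px
}

# Pooled-variance two-sample t statistic from the textbook formula.
pooled_t_oracle <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Mixed-design ANOVA sums of squares computed directly from cell means
# (balanced designs only): subjects nested in group, crossed with radius.
rm_anova_oracle <- function(df) {
  df$subject <- factor(df$subject); df$group <- factor(df$group)
  df$radius <- factor(df$radius)
  N <- nrow(df)
  gm <- mean(df$value)
  a <- nlevels(df$group); r <- nlevels(df$radius)
  s_per_g <- N / (a * r)
  m_g <- tapply(df$value, df$group, mean)
  m_r <- tapply(df$value, df$radius, mean)
  m_gr <- tapply(df$value, list(df$group, df$radius), mean)
  m_s <- tapply(df$value, df$subject, mean)
  g_of_s <- tapply(as.integer(df$group), df$subject, function(x) x[1])
  ss_group <- s_per_g * r * sum((m_g - gm)^2)
  ss_subj <- r * sum((m_s - m_g[g_of_s])^2)
  ss_radius <- s_per_g * a * sum((m_r - gm)^2)
  ss_gr <- s_per_g * sum((m_gr - matrix(m_g, a, r) -
                            matrix(m_r, a, r, byrow = TRUE) + gm)^2)
  ss_tot <- sum((df$value - gm)^2)
  ss_err_within <- ss_tot - ss_group - ss_subj - ss_radius - ss_gr
  list(ss_group = ss_group, ss_subj_error = ss_subj, ss_radius = ss_radius,
       ss_interaction = ss_gr, ss_within_error = ss_err_within,
       F_group = (ss_group / (a - 1)) / (ss_subj / (a * (s_per_g - 1))),
       F_radius = (ss_radius / (r - 1)) /
         (ss_err_within / (a * (s_per_g - 1) * (r - 1))))
}

# Small star mask: n straight ~2-px-wide arms on an empty frame (branch
# widths of 2-4 px, matching the rendered filaments).
star_mask <- function(n_arms = 6, size_px = 121, arm_px = 55,
                      px_um = 0.25, width_px = 2) {
  c0 <- (size_px + 1) / 2
  ii <- seq_len(size_px)
  m <- matrix(FALSE, size_px, size_px)
  for (k in seq_len(n_arms)) {
    th <- (k - 1) * 2 * pi / n_arms + 0.13
    dx <- outer(ii - c0, rep(1, size_px)); dy <- t(dx)
    tproj <- pmin(pmax(dx * cos(th) + dy * sin(th), 0), arm_px)
    dist <- sqrt((dx - tproj * cos(th))^2 + (dy - tproj * sin(th))^2)
    m <- m | (dist <= width_px / 2)
  }
  structure(m, pixel_size_um = px_um, class = c("binary_mask", "matrix"))
}
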