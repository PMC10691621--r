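# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or textbook formulas, without touching the code
# paths they check.

# Pixelized aperture area: rasterize the MLC/jaw field on a fine grid and
# count open pixel centers.
raster_aperture_area <- function(mlc_left, mlc_right, boundaries,
                                 jaw_x, jaw_y, h = 0.01) {
  xs <- seq(jaw_x[1] + h / 2, jaw_x[2] - h / 2, by = h)
  ys <- seq(jaw_y[1] + h / 2, jaw_y[2] - h / 2, by = h)
  pair <- findInterval(ys, boundaries, rightmost.closed = TRUE)
  ok <- pair >= 1 & pair <= length(mlc_left)
  open <- 0L
  for (iy in which(ok)) {
    p <- pair[iy]
    open <- open + sum(xs > mlc_left[p] & xs < mlc_right[p])
  }
  open * h * h
}

# Exhaustive-sort KNN: per test point, sort all training distances and take
# the plain majority of the first k labels (matching first-occurrence tie
# order via sort stability of order()).
brute_knn <- function(train_x, train_y, test_x, k) {
  apply(test_x, 1, function(p) {
    d <- sqrt(colSums((t(train_x) - p)^2))
    votes <- train_y[order(d)[seq_len(k)]]
    if (sum(votes) >= 0 && sum(votes) != 0) sign(sum(votes))
    else if (sum(votes) < 0) -1
    else NA  # vote tie: caller avoids even k
  })
}

# Textbook Welch t-test.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

z_oracle <- function(a, b) {
  z <- (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  list(statistic = z, p = 2 * pnorm(-abs(z)))
}

# Monte-Carlo polygon-stack volume via mgcv's point-in-polygon.
mc_volume <- function(contours, slice_spacing, n = 2e5) {
  xs <- range(unlist(lapply(contours, `[[`, "x")))
  ys <- range(unlist(lapply(contours, `[[`, "y")))
  box_area <- diff(xs) * diff(ys)
  total <- 0
  for (ct in contours) {
    px <- runif(n, xs[1], xs[2]); py <- runif(n, ys[1], ys[2])
    inside <- mgcv::in.out(cbind(c(ct$x, ct$x[1]), c(ct$y, ct$y[1])),
                           cbind(px, py))
    total <- total + mean(inside) * box_area * slice_spacing
  }
  total
}

# Random irregular aperture on a compact bank (for raster comparisons).
random_aperture <- function(n_pairs = 8, width = 0.5) {
  boundaries <- seq(0, by = width, length.out = n_pairs + 1) -
    n_pairs * width / 2
  left <- runif(n_pairs, -4, 0.5)
  right <- left + pmax(0, runif(n_pairs, -1, 4))  # some pairs closed
  list(left = left, right = right, boundaries = boundaries,
       jaw_x = c(-4.5, 4.5), jaw_y = c(-2.5, 2.5))
}

# Small deterministic cohort table for classifier tests: two clusters.
toy_cohort <- function(n_per_class = 10, sep = 6, seed = 99) {
  artpredict:::with_seed(seed, {
    make <- function(n, center, label, tag) {
      do.call(rbind, lapply(seq_len(n), function(i) {
        data.frame(patient_id = sprintf("%s%02d", tag, i),
                   eqif_size = rep(10, 11), bin_dose = rnorm(11, center, 1),
                   ctv_high_per_bmi = center + rnorm(1),
                   total_mu = 600 + rnorm(1, center * 10, 5),
                   oral_mean_dose = center + rnorm(1),
                   label = label)
      }))
    }
    co <- rbind(make(n_per_class, 0, -1, "n"), make(n_per_class, sep, 1, "a"))
    class(co) <- c("cohort_table", "data.frame")
    co
  })
}
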