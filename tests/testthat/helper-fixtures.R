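# small in-code fixtures and independent oracles shared across tests

make_label <- function(m, px = 10, xll = 0, yll = 0) {
  label_raster(m, px, xll, yll)
}

random_label <- function(nr, nc, seed, p = 0.5, px = 10) {
  withr::with_seed(seed, {
    make_label(matrix(rbinom(nr * nc, 1L, p), nr, nc), px)
  })
}

flat_bathy <- function(nr, nc, depth, px = 10) {
  raster_grid(matrix(depth, nr, nc), px, band_names = "depth_m")
}

# a tiny labelled feature table with a learnable rule
toy_table <- function(n = 1000, seed = 42) {
  withr::with_seed(seed, {
    tab <- data.frame(blue = runif(n, 0, 0.3), green = runif(n, 0, 0.3),
                      red = runif(n, 0, 0.3), depth = runif(n, 0, 40))
    tab$label <- as.integer(tab$depth < 20 & tab$green > 0.1)
    tab$row <- seq_len(n)
    tab$col <- rep(1L, n)
    tab
  })
}

# brute-force windowed-majority oracle for the binary median filter:
# valid cells in the truncated window, tie keeps the centre class
majority_oracle <- function(lab, window = 3L) {
  half <- (window - 1L) %/% 2L
  d <- dim(lab)
  out <- lab
  for (r in seq_len(d[1L])) for (c in seq_len(d[2L])) {
    if (is.na(lab[r, c])) next
    rs <- max(1L, r - half):min(d[1L], r + half)
    cs <- max(1L, c - half):min(d[2L], c + half)
    v <- lab[rs, cs]
    v <- v[!is.na(v)]
    n1 <- sum(v == 1)
    out[r, c] <- if (2 * n1 > length(v)) 1
      else if (2 * n1 < length(v)) 0 else lab[r, c]
  }
  out
}

# per-row affine/ReLU/sigmoid oracle, explicit scalar arithmetic
forward_oracle <- function(model, X) {
  p <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    a <- (X[i, ] - model$scaling$mean) / model$scaling$sd
    for (l in seq_along(model$weights)) {
      z <- numeric(ncol(model$weights[[l]]))
      for (j in seq_along(z))
        z[j] <- sum(a * model$weights[[l]][, j]) + model$biases[[l]][j]
      a <- if (l < length(model$weights)) pmax(z, 0) else 1 / (1 + exp(-z))
    }
    p[i] <- min(max(a, 1e-12), 1 - 1e-12)
  }
  p
}

random_tiny_model <- function(seed) {
  withr::with_seed(seed, {
    hidden <- sample(1:6, sample(0:2, 1), replace = TRUE)
    sizes <- c(4L, hidden, 1L)
    W <- list(); B <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L]), sizes[l], sizes[l + 1L])
      B[[l]] <- rnorm(sizes[l + 1L])
    }
    sc <- list(mean = rnorm(4), sd = runif(4, 0.5, 2))
    posimap:::new_model(sizes, W, B, sc)
  })
}

# quick 3-band reflectance scene over a constant-depth bottom
flat_scene <- function(habitat, depth, optics = optics_params(noise_sd = rep(0, 3)),
                       seed = 1) {
  simulate_reflectance(habitat, flat_bathy(nrow(habitat$values),
                                           ncol(habitat$values), depth),
                       optics, seed = seed)
}
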