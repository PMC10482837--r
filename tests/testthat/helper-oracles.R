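# Independent brute-force oracles used to check the package's metric and
# geometry implementations. These deliberately share no code with the
# implementations they verify.

# Dice by explicit pixel loop.
oracle_dsc <- function(a, b) {
  a <- a != 0; b <- b != 0
  inter <- 0L; na <- 0L; nb <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j]) na <- na + 1L
    if (b[i, j]) nb <- nb + 1L
    if (a[i, j] && b[i, j]) inter <- inter + 1L
  }
  if (na + nb == 0L) return(1)
  2 * inter / (na + nb)
}

# Boundary set for the oracle: foreground pixel with a 4-neighbour outside
# the foreground (or on the image edge), as 0-based coordinates.
oracle_boundary <- function(m) {
  m <- m != 0
  out <- NULL
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    edge <- i == 1 || i == nr || j == 1 || j == nc
    if (edge || !m[i - 1, j] || !m[i + 1, j] || !m[i, j - 1] || !m[i, j + 1]) {
      out <- rbind(out, c(i - 1, j - 1))
    }
  }
  out
}

# All-pairs max-min Hausdorff.
oracle_hausdorff <- function(a, b, spacing = 1) {
  P <- oracle_boundary(a); Q <- oracle_boundary(b)
  h <- function(X, Y) {
    worst <- 0
    for (i in seq_len(nrow(X))) {
      best <- Inf
      for (j in seq_len(nrow(Y))) {
        d <- sqrt(sum((X[i, ] - Y[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(h(P, Q), h(Q, P)) * spacing
}

# Closed-form circumcircle of a triangle (rows/cols as x/y).
oracle_circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# ICC(2,1) by explicit two-way ANOVA sums of squares (n subjects, 2 raters).
oracle_icc21 <- function(x, y) {
  n <- length(x); k <- 2
  grand <- mean(c(x, y))
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((c(x, y) - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Lin's CCC with 1/n moments, written out directly.
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Random connected-ish blob mask for metric tests (always non-empty).
random_mask <- function(nr, nc, p = 0.25) {
  m <- matrix(stats::runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(nr, 1), sample(nc, 1)] <- TRUE
  m
}

# Standard small phantom case cache so several test files can share one.
phantom_fixture <- local({
  cache <- new.env()
  function(seed = 1, population = "normal", jitter = 0) {
    key <- paste(seed, population, jitter, sep = "_")
    if (is.null(cache[[key]])) {
      spec <- sample_phantom_spec(seed, population)
      case <- generate_phantom(spec)
      if (jitter > 0) case <- add_boundary_jitter(case, jitter, seed = seed + 5000)
      cache[[key]] <- case
    }
    cache[[key]]
  }
})
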