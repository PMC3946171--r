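# Shared fixtures and independent oracles, built in code at test time.

# recursive cofactor-expansion determinant: independent oracle for the
# log-determinant / determinant-lemma checks
cofactor_det <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m[1L, 1L])
  if (n == 2L) return(m[1L, 1L] * m[2L, 2L] - m[1L, 2L] * m[2L, 1L])
  sum(vapply(seq_len(n), function(j) {
    (-1)^(1 + j) * m[1L, j] * cofactor_det(m[-1L, -j, drop = FALSE])
  }, numeric(1)))
}

# plug-in mutual information computed by explicit double loop (oracle for
# mrmr_select's internal estimate)
mi_oracle <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  n <- length(a)
  total <- 0
  for (x in ua) {
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) {
        total <- total + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
      }
    }
  }
  total
}

# small standardized design with intercept column
toy_design <- function(X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  cbind(`(Intercept)` = 1, X)
}

# filled-circle label map
circle_map <- function(h, w, cy, cx, r, id = 1L) {
  m <- matrix(0L, h, w)
  for (row in seq_len(h)) {
    for (col in seq_len(w)) {
      if ((row - cy)^2 + (col - cx)^2 <= r^2) m[row, col] <- id
    }
  }
  m
}

# filled-rectangle label map
rect_map <- function(h, w, r0, r1, c0, c1, id = 1L) {
  m <- matrix(0L, h, w)
  m[r0:r1, c0:c1] <- id
  m
}

# count foreground pixels with no 4-connected foreground neighbor
isolated_pixel_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  nb <- pad[1:h, 2:(w + 1L)] | pad[3:(h + 2L), 2:(w + 1L)] |
    pad[2:(h + 1L), 1:w] | pad[2:(h + 1L), 3:(w + 2L)]
  sum(mask & !nb)
}

# the standard synthetic tabular benchmark (4 informative / 40 noise,
# effect size 2, n = 1000)
standard_benchmark <- function(seed = 1L) {
  make_feature_dataset(tabular_spec(seed = seed))
}

small_pool <- function(n = 120, seed = 3L) {
  make_feature_dataset(tabular_spec(n_cells = n, n_informative = 2,
                                    n_noise = 4, effect_size = 2,
                                    seed = seed))
}
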