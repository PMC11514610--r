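# Independent brute-force oracles, written straight from the definitions
# and kept free of the package's own code paths.

# AUC as explicit all-pairs concordance with ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# MSS threshold by exhaustive scan over all distinct observed scores
oracle_mss <- function(scores, labels) {
  best_t <- NA_real_
  best_v <- -Inf
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    v <- sens + spec
    if (v > best_v) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Straight-line scalar implementation of the 19 bioclimatic variables for
# one cell: explicit loops over months and the 12 wrap-around quarters.
oracle_bioclim_cell <- function(tmin, tmax, prcp) {
  tavg <- (tmin + tmax) / 2
  qmeans <- numeric(12)
  qprcp <- numeric(12)
  for (q in 1:12) {
    months <- ((q - 1) + 0:2) %% 12 + 1
    qmeans[q] <- mean(tavg[months])
    qprcp[q] <- sum(prcp[months])
  }
  wettest <- which.max(qprcp)
  driest <- which.min(qprcp)
  warmest <- which.max(qmeans)
  coldest <- which.min(qmeans)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  bio5 <- max(tmax)
  bio6 <- min(tmin)
  bio2 <- mean(tmax - tmin)
  bio7 <- bio5 - bio6
  c(bio1 = mean(tavg),
    bio2 = bio2,
    bio3 = if (bio7 > 0) bio2 / bio7 * 100 else NA_real_,
    bio4 = pop_sd(tavg) * 100,
    bio5 = bio5, bio6 = bio6, bio7 = bio7,
    bio8 = qmeans[wettest], bio9 = qmeans[driest],
    bio10 = qmeans[warmest], bio11 = qmeans[coldest],
    bio12 = sum(prcp), bio13 = max(prcp), bio14 = min(prcp),
    bio15 = 100 * pop_sd(prcp) / (1 + mean(prcp)),
    bio16 = qprcp[wettest], bio17 = qprcp[driest],
    bio18 = qprcp[warmest], bio19 = qprcp[coldest])
}

# monthly_climate whose 36 grids hold one cell per random series row
oracle_climate_grids <- function(tmin_mat, tmax_mat, prcp_mat) {
  n <- nrow(tmin_mat)
  as_grids <- function(m) {
    lapply(1:12, function(j) raster_grid(matrix(m[, j], n, 1)))
  }
  monthly_climate(as_grids(tmin_mat), as_grids(tmax_mat),
                  as_grids(prcp_mat))
}

# Moran-style lag-1 autocorrelation of a matrix (horizontal + vertical)
lag1_autocor <- function(m) {
  h <- stats::cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
  v <- stats::cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
  (h + v) / 2
}
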