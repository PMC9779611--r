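# Independent oracles used across the suite. These deliberately take a
# different computational route from the package code they check.

# Brute-force PROSITE matcher: expands a compiled pattern into every
# concrete fixed-length regular expression (one per repeat assignment)
# and, at each start, takes the longest expansion that matches. Uses R's
# regex engine, not the package matcher.
oracle_scan <- function(pattern, sequence) {
  el_regex <- function(el) {
    switch(el$type,
           any = "[A-Z]",
           res = el$residues,
           set = paste0("[", el$residues, "]"),
           exclude = paste0("[^", el$residues, "]"))
  }
  expansions <- list(list(rx = "", len = 0L))
  for (el in pattern$elements) {
    rx1 <- el_regex(el)
    expansions <- unlist(lapply(expansions, function(e) {
      lapply(seq(el$min, el$max), function(k) {
        list(rx = paste0(e$rx, strrep(rx1, k)), len = e$len + k)
      })
    }), recursive = FALSE)
  }
  n <- nchar(sequence)
  starts <- if (pattern$anchor_n) 1L else seq_len(n)
  hits <- list()
  for (s in starts) {
    best <- -1L
    for (e in expansions) {
      if (e$len == 0L) next
      end <- s + e$len - 1L
      if (end > n) next
      if (pattern$anchor_c && end != n) next
      if (grepl(paste0("^", e$rx, "$"), substr(sequence, s, end))) {
        best <- max(best, end)
      }
    }
    if (best >= s) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, end = best, matched = substr(sequence, s, best),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# Kabsch oracle via the singular-value identity: the minimal rmsd is
# sqrt((E0 - 2 * (s1 + s2 +/- s3)) / n) where E0 is the total centered
# squared norm and s are the singular values of the cross-covariance
# (sign of s3 flips when the unconstrained optimum is a reflection).
# Never constructs the rotation.
oracle_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  E0 <- sum(A0^2) + sum(B0^2)
  s <- svd(crossprod(B0, A0))
  sign3 <- sign(det(s$u) * det(s$v))
  tr <- s$d[1] + s$d[2] + sign3 * s$d[3]
  sqrt(max(0, E0 - 2 * tr) / nrow(A))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_motion_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% R + matrix(t, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# random intra-chain disulfide topology spec: n_cys cysteines, floor(k)
# bonded pairs drawn at random, rest free
random_topology_spec <- function(n_cys) {
  n_pairs <- sample(0:(n_cys %/% 2L), 1L)
  ords <- sample(n_cys)
  pairs <- list()
  if (n_pairs > 0L) {
    for (k in seq_len(n_pairs)) {
      pairs[[k]] <- c(sort(ords[c(2 * k - 1, 2 * k)]), 2.05)
    }
  }
  pairs
}
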