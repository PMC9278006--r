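# Independent brute-force / closed-form oracles used to cross-check the
# package's implementations, plus small fixture builders.

withr_local_tempfile <- function(ext = ".pdb") {
  f <- tempfile(fileext = ext)
  withr::defer(unlink(f), envir = parent.frame())
  f
}

# Horn's quaternion closed-form minimum RMSD between two point sets
# (independent of the SVD route used by the package)
quaternion_rmsd <- function(moving, fixed) {
  p <- sweep(moving, 2, colMeans(moving))
  q <- sweep(fixed, 2, colMeans(fixed))
  s <- crossprod(p, q)
  k <- matrix(0, 4, 4)
  k[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  k[1, 2] <- k[2, 1] <- s[2, 3] - s[3, 2]
  k[1, 3] <- k[3, 1] <- s[3, 1] - s[1, 3]
  k[1, 4] <- k[4, 1] <- s[1, 2] - s[2, 1]
  k[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  k[2, 3] <- k[3, 2] <- s[1, 2] + s[2, 1]
  k[2, 4] <- k[4, 2] <- s[3, 1] + s[1, 3]
  k[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  k[3, 4] <- k[4, 3] <- s[2, 3] + s[3, 2]
  k[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(p^2) + sum(q^2) - 2 * lam) / nrow(p)))
}

# exhaustive all-atom double loop residue contact enumeration
brute_force_contacts <- function(complex, cutoff) {
  a <- complex$atoms
  rec <- a[a$chain %in% complex$receptor_chains, ]
  lig <- a[a$chain %in% complex$ligand_chains, ]
  found <- character(0)
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      if (d <= cutoff) found <- c(found, paste(rec$key[i], lig$key[j]))
    }
  }
  sort(unique(found))
}

# exhaustive concordant-pair AUC (ties count one half)
brute_force_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
exact_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_stat(seq_len(n1))
  mid <- n1 * (length(y)) / 2
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, u_stat)
  mean(abs(stats - mid) >= abs(obs - mid) - 1e-9)
}

# greedy identity clustering computed from a precomputed all-pairs
# identity matrix (independent of the package's incremental route)
brute_force_neff <- function(rows, threshold) {
  chars <- strsplit(rows, "")
  n <- length(rows)
  ident <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- chars[[i]]; b <- chars[[j]]
      m <- sum(a != "-" & b != "-" & a == b)
      den <- min(sum(a != "-"), sum(b != "-"))
      ident[i, j] <- if (den == 0) 0 else m / den
    }
  }
  unglen <- sapply(chars, function(ch) sum(ch != "-"))
  ord <- order(-unglen)
  reps <- integer(0)
  for (i in ord) {
    hit <- FALSE
    for (r in reps) {
      if (ident[i, r] >= threshold - 1e-12) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, i)
  }
  length(reps)
}

# CA-only complex with arbitrary one-letter sequences on a line, for
# alignment/mapping tests (CA counts as a backbone atom)
make_seq_complex <- function(seq_rec, seq_lig, resno_rec = NULL,
                             resno_lig = NULL, offset = c(0, 0, 0)) {
  aa_rec <- strsplit(seq_rec, "")[[1]]
  aa_lig <- strsplit(seq_lig, "")[[1]]
  if (is.null(resno_rec)) resno_rec <- seq_along(aa_rec)
  if (is.null(resno_lig)) resno_lig <- seq_along(aa_lig)
  df <- rbind(
    data.frame(chain = "A", resno = resno_rec, ins = "",
               resid = bio3d::aa123(aa_rec), elety = "CA",
               x = 3.8 * seq_along(aa_rec), y = 0, z = 0,
               o = 1, b = 80, stringsAsFactors = FALSE),
    data.frame(chain = "B", resno = resno_lig, ins = "",
               resid = bio3d::aa123(aa_lig), elety = "CA",
               x = 3.8 * seq_along(aa_lig) + offset[1], y = 5 + offset[2],
               z = offset[3], o = 1, b = 80, stringsAsFactors = FALSE))
  complex_structure(df, "A", "B", label = "seqtoy")
}

# random alignment rows over a small alphabet, query first (no gaps)
random_alignment <- function(n_rows, len, seed, alphabet = c("A", "C", "D",
                                                             "E", "F", "G"),
                             gap_prob = 0.15) {
  set.seed(seed)
  rows <- vapply(seq_len(n_rows), function(i) {
    ch <- sample(alphabet, len, replace = TRUE)
    if (i > 1) {
      gaps <- stats::runif(len) < gap_prob
      ch[gaps] <- "-"
    }
    paste(ch, collapse = "")
  }, character(1))
  msa_alignment(rows)
}
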