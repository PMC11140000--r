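# Independent oracles: deliberately written as plain, slow loops so they
# share no code path with the implementations they check.

# Six-frame stop-to-stop ORF enumeration by direct position scanning.
oracle_orfs <- function(seq, min_len_nt) {
  seq <- toupper(seq)
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  L <- nchar(seq)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (frame in 0:2) {
      aa <- character(0)
      pos <- frame + 1L
      while (pos + 2L <= L) {
        cod <- substr(s, pos, pos + 2L)
        aa <- c(aa, if (grepl("[^ACGT]", cod)) NA_character_
                    else unname(gc[cod]))
        pos <- pos + 3L
      }
      if (!length(aa)) next
      brk <- c(0L, which(is.na(aa) | aa == "*"), length(aa) + 1L)
      for (b in seq_len(length(brk) - 1L)) {
        c0 <- brk[b] + 1L
        c1 <- brk[b + 1L] - 1L
        if (c1 < c0) next
        nc <- c1 - c0 + 1L
        if (3L * nc < min_len_nt) next
        s0 <- frame + 3L * (c0 - 1L)
        e0 <- s0 + 3L * nc
        if (strand == "+") iv <- c(s0, e0) else iv <- c(L - e0, L - s0)
        out[[length(out) + 1L]] <- list(
          strand = strand, start = iv[1], end = iv[2],
          protein = paste(aa[c0:c1], collapse = ""))
      }
    }
  }
  out
}

# Affine-gap Smith-Waterman score by explicit 3-state recursion.
# Gap of length L costs open + L * ext (the BLAST/Biostrings convention
# the package follows).
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      h_prev <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0)
      M[i, j] <- h_prev + mat[av[i - 1], bv[j - 1]]
      X[i, j] <- max(max(M[i - 1, j], Y[i - 1, j], 0) - open - ext,
                     X[i - 1, j] - ext)
      Y[i, j] <- max(max(M[i, j - 1], X[i, j - 1], 0) - open - ext,
                     Y[i, j - 1] - ext)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# Glocal (pattern-global, subject-local) alignment identity with full
# traceback, for the clustering oracle. Scoring matches the package's
# clustering parameters.
oracle_glocal_identity <- function(pattern, subject,
                                   match = 1, mismatch = -2,
                                   open = 4, ext = 2) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  H <- matrix(NEG, m + 1, n + 1)
  X <- H; Y <- H
  H[1, ] <- 0
  for (i in 2:(m + 1)) {
    X[i, 1] <- max(H[i - 1, 1] - open - ext, X[i - 1, 1] - ext)
    H[i, 1] <- X[i, 1]
    for (j in 2:(n + 1)) {
      sc <- if (p[i - 1] == s[j - 1]) match else mismatch
      D <- H[i - 1, j - 1] + sc
      X[i, j] <- max(H[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(H[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      H[i, j] <- max(D, X[i, j], Y[i, j])
    }
  }
  jbest <- which.max(H[m + 1, ])
  # traceback counting matches and columns
  i <- m + 1; j <- jbest
  matches <- 0L; cols <- 0L
  state <- "H"
  while (i > 1) {
    if (j > 1 && H[i, j] == H[i - 1, j - 1] +
          (if (p[i - 1] == s[j - 1]) match else mismatch)) {
      matches <- matches + (p[i - 1] == s[j - 1])
      cols <- cols + 1L; i <- i - 1L; j <- j - 1L
    } else if (H[i, j] == X[i, j]) {
      # gap in subject; walk up while in X
      while (i > 1 && X[i, j] == X[i - 1, j] - ext &&
             X[i - 1, j] > NEG / 2) {
        cols <- cols + 1L; i <- i - 1L
      }
      cols <- cols + 1L; i <- i - 1L
    } else {
      while (j > 1 && Y[i, j] == Y[i, j - 1] - ext &&
             Y[i, j - 1] > NEG / 2) {
        cols <- cols + 1L; j <- j - 1L
      }
      cols <- cols + 1L; j <- j - 1L
    }
  }
  list(identity = matches / cols, score = H[m + 1, jbest],
       matches = matches, columns = cols)
}

# Exact conditional binomial test (Poisson-limit oracle for the NB exact
# test at phi = 0): condition on T = a + b, success probability
# n_a / (n_a + n_b), two-sided by summing outcomes no more likely than
# the observed one.
oracle_binom_p <- function(a, b, n_a, n_b) {
  tt <- a + b
  if (tt == 0) return(1)
  pr <- stats::dbinom(0:tt, tt, n_a / (n_a + n_b))
  sum(pr[pr <= pr[a + 1] * (1 + 1e-9)]) / sum(pr)
}

# Classical-scaling oracle: double-centre the squared distances and
# eigen-decompose.
oracle_cmds <- function(D, k = 2) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  e$vectors[, 1:k, drop = FALSE] %*% diag(sqrt(pmax(e$values[1:k], 0)), k)
}

random_dna_str <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                    collapse = "")
random_aa_str <- function(n) paste(sample(c("A","R","N","D","C","Q","E","G",
                                            "H","I","L","K","M","F","P","S",
                                            "T","W","Y","V"), n, TRUE),
                                   collapse = "")
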