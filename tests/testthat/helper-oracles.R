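# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Hand-enumerated truth table for the crosstalk classification over the
# full categorical grid (phospho x glyc x conserved).
oracle_classify <- function(phos, glyc, conserved) {
  if (phos == "above" && !is.na(glyc) && glyc == "above") {
    return("yy_positive")
  }
  if (conserved) {
    if (phos == "above" && !is.na(glyc) && glyc == "near") {
      return("yy_false_negative")
    }
    if (!is.na(glyc) && glyc == "above" && phos == "near") {
      return("yy_false_negative")
    }
  }
  if (phos == "above") return("phospho_only")
  if (!is.na(glyc) && glyc == "above") return("glyc_only")
  "none"
}

# Plain Needleman-Wunsch with a LINEAR gap penalty, filled cell by cell.
# Scores only; used to check align_global(gap_open = 0).
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  f <- matrix(0, n + 1, m + 1)
  f[, 1] <- -gap * (0:n)
  f[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      f[i + 1, j + 1] <- max(f[i, j] + s, f[i, j + 1] - gap,
                             f[i + 1, j] - gap)
    }
  }
  f[n + 1, m + 1]
}

# Identity-style substitution matrix over an arbitrary alphabet.
toy_submat <- function(alphabet = LETTERS, match = 1, mismatch = -1) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

# Column of the ungapped_pos-th residue by naive left-to-right counting.
oracle_map_position <- function(gapped, ungapped_pos) {
  chars <- strsplit(gapped, "")[[1]]
  seen <- 0
  for (col in seq_along(chars)) {
    if (chars[col] != "-") {
      seen <- seen + 1
      if (seen == ungapped_pos) return(col)
    }
  }
  NA_integer_
}

# Minimal random kinase motif over a restricted alphabet; zero weights
# for the center row except the target residues.
random_motif <- function(name = "toy", alphabet = c("A", "C", "D"),
                         targets = "S", seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, 15, 20, dimnames = list(NULL, ptmtalk:::AA_STANDARD))
    w[, alphabet] <- round(runif(15 * length(alphabet), -2, 2), 3)
    w[8, ] <- 0
    w[8, targets] <- 1
    kinase_motif(name, w, target_residues = targets)
  })
}

# A small two-row toy msa
toy_msa <- function() new_msa(c("q", "o"), c("MK-T", "MKST"))
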