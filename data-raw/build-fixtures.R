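# Builds the packaged synthetic sequence fixtures under inst/extdata/.
#
# The shipped FoxO3/ortholog/FoxO1 sequences are SYNTHETIC STAND-INS, not the
# UniProt/RefSeq entries whose accessions they echo. They are constructed so
# that every curated PTM site position carries the right residue letter and
# every published flanking window appears verbatim at its printed coordinates;
# everything else is seeded random background. Re-running this script
# reproduces the files byte-identically.

set.seed(29183205)

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
LEN <- 673

# background composition: roughly average globular-protein frequencies
comp <- c(A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039, G = 0.071,
          H = 0.023, I = 0.059, K = 0.058, L = 0.097, M = 0.024, N = 0.041,
          P = 0.047, Q = 0.040, R = 0.055, S = 0.066, T = 0.053, V = 0.069,
          W = 0.011, Y = 0.029)
comp <- comp / sum(comp)

seq3 <- sample(AA, LEN, replace = TRUE, prob = comp[AA])
seq3[1] <- "M"

put <- function(s, start, str) {
  ch <- strsplit(str, "")[[1]]
  s[start + seq_along(ch) - 1L] <- ch
  s
}

# published flanking windows, anchored at their 1-based start coordinates
seq3 <- put(seq3, 142, "GGSGQPRKCSSRR")       # K149 window
seq3 <- put(seq3, 200, "SNSSAGWKNSIRH")       # K207 / S209 window
seq3 <- put(seq3, 241, "GKSGKAPRRRAVSMD")     # R248/R250 AKT-motif region, S253
seq3 <- put(seq3, 258, "NKYTKSRGRAAKKKAALQ")  # R264/R266/K270/K271 region
seq3 <- put(seq3, 562, "SSSLGSAKHQQQS")       # K569 region

# residue letters at every curated site position
ser <- c(7, 12, 26, 30, 43, 48, 55, 110, 144, 151, 152, 161, 172, 173, 200,
         209, 243, 253, 257, 280, 284, 294, 297, 299, 300, 311, 315, 318, 321,
         325, 330, 344, 349, 350, 351, 353, 355, 357, 359, 399, 402, 411, 413,
         421, 425, 428, 429, 432, 442, 446, 463, 476, 480, 482, 494, 497, 501,
         547, 551, 553, 560, 563, 564, 567, 574, 577, 584, 586, 588, 591, 594,
         609, 626, 644, 666, 667, 669)
thr <- c(32, 228, 276, 296, 331, 395, 404, 417, 418, 450, 469, 487, 498, 540,
         582, 660)
tyr <- c(162, 260, 416, 465)
arg <- c(248, 249, 250, 264, 266)
lys <- c(149, 207, 262, 270, 271, 569)
seq3[ser] <- "S"; seq3[thr] <- "T"; seq3[tyr] <- "Y"
seq3[arg] <- "R"; seq3[lys] <- "K"

protected <- sort(unique(c(1L, ser, thr, tyr, arg, lys,
                           142:154, 200:212, 241:255, 258:275, 562:574)))
nonconserved_sites <- c(395L, 404L, 418L)
mutable <- setdiff(seq_len(LEN), setdiff(protected, nonconserved_sites))

mutate_at <- function(s, pos) {
  for (p in pos) s[p] <- sample(setdiff(AA, s[p]), 1L)
  s
}

# four ortholog stand-ins: substitution-only (no indels), conserved at every
# site position except T395/T404/T418, which diverge in every ortholog
orth_ids <- c("NP_001129431.1", "NP_001099865.1", "NP_062714.1", "XP_615634.2")
orth_org <- c("Sus scrofa", "Rattus norvegicus", "Mus musculus", "Bos taurus")
orths <- lapply(seq_along(orth_ids), function(i) {
  pos <- mutable[runif(length(mutable)) < 0.08]
  pos <- sort(unique(c(pos, nonconserved_sites)))
  mutate_at(seq3, pos)
})

# FoxO1 stand-in: keep 140-290 (site-mapping region) intact, mutate 10% of the
# remaining background, delete a 21-residue block at 601-621 -> length 652
fox1 <- seq3
keep <- unique(c(protected, 140:290))
f1_mutable <- setdiff(seq_len(LEN), keep)
fox1 <- mutate_at(fox1, f1_mutable[runif(length(f1_mutable)) < 0.10])
fox1 <- fox1[-(601:621)]

write_fa <- function(path, ids, descs, seqs, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i], " ", descs[i]), con)
    s <- paste(seqs[[i]], collapse = "")
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(1, nchar(s), width) + width - 1, nchar(s))),
               con)
  }
}

out <- "inst/extdata"
write_fa(file.path(out, "foxo3_synthetic.fasta"),
         "O43524", "synthetic stand-in for human FoxO3 (FOXO3_HUMAN)",
         list(seq3))
write_fa(file.path(out, "foxo3_orthologs_synthetic.afa"),
         c("O43524", orth_ids),
         c("synthetic stand-in for human FoxO3 (FOXO3_HUMAN)",
           paste("synthetic stand-in FoxO3 ortholog,", orth_org)),
         c(list(seq3), orths))
write_fa(file.path(out, "foxo1_synthetic.fasta"),
         "NP_062713.2", "synthetic stand-in for mouse FoxO1",
         list(fox1))
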