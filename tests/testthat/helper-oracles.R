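# Independent oracles used by the tests.  These deliberately avoid the
# package's own machinery: motif matching is plain-regex over character
# strings, and circular arithmetic is done longhand.

IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(motif) {
  paste(IUPAC_CLASS[strsplit(motif, "")[[1L]]], collapse = "")
}

revcomp_chr <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

# all motif start positions (1..N, circular) via regex over the doubled string
oracle_motif_starts <- function(bases, motif) {
  N <- nchar(bases)
  doubled <- paste0(bases, bases)
  rx <- paste0("(?=", iupac_regex(motif), ")")
  m <- gregexpr(rx, doubled, perl = TRUE)[[1L]]
  s <- as.integer(m[m > 0])
  sort(unique(s[s <= N]))
}

# top-strand scission positions by brute force, both strands
oracle_find_cuts <- function(bases, motif, off_top, off_bottom,
                             nicking = FALSE) {
  N <- nchar(bases)
  wrap <- function(p) ((p - 1L) %% N) + 1L
  cuts <- wrap(oracle_motif_starts(bases, motif) + off_top - 1L)
  if (!nicking) {
    s_rev <- oracle_motif_starts(bases, revcomp_chr(motif))
    ends <- s_rev + nchar(motif) - 1L
    cuts <- c(cuts, wrap(ends - off_bottom))
  }
  sort(unique(as.integer(cuts)))
}

# rotate a circular sequence's origin left by r bases
rotate_bases <- function(bases, r) {
  N <- nchar(bases)
  r <- r %% N
  if (r == 0) return(bases)
  paste0(substr(bases, r + 1L, N), substr(bases, 1L, r))
}

# where position p (old origin) lands after rotating the origin left by r
rotate_position <- function(p, r, N) ((p - r - 1) %% N) + 1

# shortest circular distance in bp
circ_dist_bp <- function(a, b, N) {
  d <- abs(a - b) %% N
  pmin(d, N - d)
}

std_map <- function(size = "336") {
  restriction_map(minicircle_sequence(size),
                  c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI"))
}
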