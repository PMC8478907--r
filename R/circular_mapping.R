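# Restriction mapping and cleavage-site triangulation on circular DNA.
#
# Coordinates are 1-based positions 1..N on the top strand; "a cut at p"
# means scission of the top strand between bases p and p+1 (mod N).  A
# measured fragment of length L against a reference cut at r is
# compatible with an unknown cut at (r + L) mod N or (r - L) mod N;
# candidates from many (enzyme, direction) combinations are clustered on
# the circle and summarised by circular mean and circular sd.

#' A named circular DNA sequence
#'
#' @param bases A character string over the IUPAC alphabet restricted to
#'   `A`, `C`, `G`, `T`, `N`; lower case is accepted and upper-cased.
#' @param name Sequence label.
#' @return An object of class `circular_sequence`: a list with `name`,
#'   `bases` (upper case) and `length`.
#' @examples
#' circular_sequence("AATTAATT", "tiny")
#' @export
circular_sequence <- function(bases, name = "circle") {
  if (!is.character(bases) || length(bases) != 1L || nchar(bases) < 1L)
    stop("'bases' must be a single non-empty string", call. = FALSE)
  bases <- toupper(bases)
  bad <- regmatches(bases, regexpr("[^ACGTN]", bases))
  if (length(bad) > 0L)
    stop("invalid base '", bad, "' at position ",
         regexpr("[^ACGTN]", bases), call. = FALSE)
  structure(list(name = as.character(name), bases = bases,
                 length = nchar(bases)),
            class = "circular_sequence")
}

#' @export
print.circular_sequence <- function(x, ...) {
  cat(sprintf("circular sequence '%s': %d bp\n", x$name, x$length))
  invisible(x)
}

#' Restriction / nicking enzyme specification
#'
#' Describes where an enzyme cuts relative to its recognition motif.
#' Offsets count bases from the motif start to the scission point on
#' each strand, in top-strand coordinates of the site: an offset of `k`
#' means scission between site positions `k` and `k + 1`.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC motif; degenerate codes allowed.
#' @param cut_offset_top Bases from motif start to the top-strand
#'   scission (0..motif length).
#' @param cut_offset_bottom Same for the bottom strand; ignored for
#'   nicking enzymes.
#' @param nicking If `TRUE` the enzyme nicks the top strand of the
#'   motif-bearing orientation only.
#' @return An object of class `enzyme_spec`.
#' @examples
#' enzyme_spec("EcoRV", "GATATC", 3, 3)      # blunt cutter GAT^ATC
#' enzyme_spec("Nb.BbvCI", "CCTCAGC", 2, nicking = TRUE)
#' @export
enzyme_spec <- function(name, recognition, cut_offset_top,
                        cut_offset_bottom = cut_offset_top,
                        nicking = FALSE) {
  recognition <- toupper(recognition)
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1L]]
  chars <- strsplit(recognition, "")[[1L]]
  bad <- setdiff(chars, iupac)
  if (length(bad) > 0L)
    stop("invalid IUPAC code '", bad[1L], "' in recognition motif of ",
         name, call. = FALSE)
  L <- nchar(recognition)
  if (cut_offset_top < 0 || cut_offset_top > L)
    stop("'cut_offset_top' must lie within the motif (0..", L, ")",
         call. = FALSE)
  if (!nicking && (cut_offset_bottom < 0 || cut_offset_bottom > L))
    stop("'cut_offset_bottom' must lie within the motif (0..", L, ")",
         call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = as.integer(cut_offset_top),
                 cut_offset_bottom = if (nicking) NA_integer_
                                     else as.integer(cut_offset_bottom),
                 nicking = isTRUE(nicking)),
            class = "enzyme_spec")
}

#' Built-in enzyme table
#'
#' REBASE-style definitions for the enzymes used as sequence markers on
#' the minicircles: EcoRV (GAT^ATC), XmnI (GAANN^NNTTC), NdeI
#' (CA^TATG), MseI (T^TAA), BbvCI (CC^TCAGC top, 3-nt 5' overhang) and
#' the nicking variant Nb.BbvCI. User-supplied [enzyme_spec()] objects
#' may override or extend this table anywhere an enzyme list is taken.
#'
#' @return Named list of `enzyme_spec` objects.
#' @export
builtin_enzymes <- function() {
  list(
    EcoRV = enzyme_spec("EcoRV", "GATATC", 3, 3),
    XmnI  = enzyme_spec("XmnI", "GAANNNNTTC", 5, 5),
    NdeI  = enzyme_spec("NdeI", "CATATG", 2, 4),
    MseI  = enzyme_spec("MseI", "TTAA", 1, 3),
    BbvCI = enzyme_spec("BbvCI", "CCTCAGC", 2, 5),
    Nb.BbvCI = enzyme_spec("Nb.BbvCI", "CCTCAGC", 2, nicking = TRUE))
}

# map arbitrary integers onto circle coordinates 1..N
wrap_pos <- function(p, N) ((p - 1L) %% N) + 1L

#' Find the cut positions of an enzyme on a circular sequence
#'
#' Scans both strands (top strand only for nicking enzymes) for the
#' recognition motif, including matches that wrap across the sequence
#' origin, and returns the top-strand scission coordinates: a cut at
#' `p` severs the top strand between bases `p` and `p + 1` (mod N).
#'
#' @param seq A [circular_sequence()].
#' @param enzyme An [enzyme_spec()], or the name of a [builtin_enzymes()]
#'   entry.
#' @return Sorted, deduplicated integer positions in `1..N`; integer(0)
#'   if the motif is absent.
#' @examples
#' tiny <- circular_sequence("AATTAATT")
#' find_cut_positions(tiny, enzyme_spec("MseI", "TTAA", 1, 3))
#' @export
find_cut_positions <- function(seq, enzyme) {
  stopifnot(inherits(seq, "circular_sequence"))
  if (is.character(enzyme)) {
    tab <- builtin_enzymes()
    if (!enzyme %in% names(tab))
      stop("unknown enzyme '", enzyme, "'; supply an enzyme_spec()",
           call. = FALSE)
    enzyme <- tab[[enzyme]]
  }
  stopifnot(inherits(enzyme, "enzyme_spec"))
  N <- seq$length
  motif <- Biostrings::DNAString(enzyme$recognition)
  L <- length(motif)
  if (L > N) return(integer(0))
  # doubled subject captures motifs wrapping the origin; keep starts in 1..N
  doubled <- Biostrings::DNAString(paste0(seq$bases, seq$bases))
  starts_of <- function(pat) {
    hits <- Biostrings::matchPattern(pat, doubled, fixed = FALSE)
    s <- BiocGenerics::start(hits)
    s[s <= N]
  }
  cuts <- wrap_pos(starts_of(motif) + enzyme$cut_offset_top - 1L, N)
  if (!enzyme$nicking) {
    rc <- Biostrings::reverseComplement(motif)
    s_rev <- starts_of(rc)
    ends <- s_rev + L - 1L
    cuts <- c(cuts, wrap_pos(ends - enzyme$cut_offset_bottom, N))
  }
  sort(unique(as.integer(cuts)))
}

#' Build a restriction map of a circular sequence
#'
#' @param seq A [circular_sequence()].
#' @param enzymes A character vector of [builtin_enzymes()] names, or a
#'   (possibly named) list of [enzyme_spec()] objects.
#' @return An object of class `restriction_map`: a list with the
#'   sequence and a data.frame `entries` of columns `enzyme`,
#'   `position` (one row per cut, sorted by position).
#' @examples
#' mc <- minicircle_sequence("336")
#' restriction_map(mc, c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI"))
#' @export
restriction_map <- function(seq, enzymes = names(builtin_enzymes())) {
  if (is.character(enzymes)) enzymes <- as.list(enzymes)
  rows <- lapply(enzymes, function(e) {
    pos <- find_cut_positions(seq, e)
    nm <- if (inherits(e, "enzyme_spec")) e$name else e
    if (length(pos) == 0L) return(NULL)
    data.frame(enzyme = nm, position = pos)
  })
  entries <- do.call(rbind, rows)
  if (is.null(entries))
    entries <- data.frame(enzyme = character(0), position = integer(0))
  if (anyDuplicated(entries))
    stop("duplicate (enzyme, position) entries", call. = FALSE)
  entries <- entries[order(entries$position), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(sequence = seq, entries = entries),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat(sprintf("restriction map of '%s' (%d bp): %d cut(s)\n",
              x$sequence$name, x$sequence$length, nrow(x$entries)))
  print(x$entries)
  invisible(x)
}

#' Fragment lengths from cuts on a circle
#'
#' `k` cuts on a circle yield `k` fragments whose lengths are the
#' successive circular gaps between sorted cut positions; a single cut
#' linearises the circle into one fragment of length `N`. Lengths
#' always sum to `N`.
#'
#' @param cuts Integer cut positions in `1..N` (at least one).
#' @param N Circle size in bp.
#' @return Integer fragment lengths, in the circular order of the
#'   sorted cuts (fragment i runs from cut i to the next cut).
#' @examples
#' fragment_lengths(c(41, 143), 336)  # 102 and 234
#' @export
fragment_lengths <- function(cuts, N) {
  if (length(cuts) < 1L) stop("need >= 1 cut", call. = FALSE)
  if (any(cuts < 1L | cuts > N)) stop("cuts must lie in 1..N", call. = FALSE)
  cuts <- sort(unique(as.integer(cuts)))
  if (length(cuts) == 1L) return(as.integer(N))
  gaps <- diff(c(cuts, cuts[1L] + N))
  as.integer(gaps)
}

## ---- circular statistics -------------------------------------------------

# signed shortest displacement from a to b on a circle of size N, in (-N/2, N/2]
circ_delta <- function(a, b, N) {
  d <- (b - a) %% N
  ifelse(d > N / 2, d - N, d)
}

#' Circular mean and dispersion of positions on a circle
#'
#' Positions `p` are mapped to angles `2*pi*p/N` and vector-averaged;
#' the mean direction is mapped back to `(0, N]` and the circular
#' standard deviation `sqrt(-2 log R)` is rescaled to base pairs by
#' `N / (2*pi)`.
#'
#' @param positions Numeric positions (interpreted mod `N`).
#' @param N Circle size in bp.
#' @return List with `mean` (position in `(0, N]`) and `sd_bp`.
#' @export
circular_mean_bp <- function(positions, N) {
  theta <- 2 * pi * positions / N
  z <- complex(real = mean(cos(theta)), imaginary = mean(sin(theta)))
  R <- Mod(z)
  mu <- (Arg(z) / (2 * pi) * N) %% N
  if (mu == 0) mu <- N
  sd_bp <- if (R >= 1) 0 else sqrt(-2 * log(R)) * N / (2 * pi)
  list(mean = mu, sd_bp = sd_bp)
}

#' Triangulate nuclease cleavage sites from fragment-length observations
#'
#' Each observed fragment of length `L`, measured from a digest in
#' which a reference enzyme cut at position `r`, is compatible with a
#' nuclease cut at `(r + L) mod N` or `(r - L) mod N` — gels do not
#' reveal the direction. Candidate positions from all observations and
#' reference cuts are pooled and clustered on the circle; clusters
#' supported by enough distinct reference enzymes become site
#' estimates, located at the circular mean of their candidates with the
#' circular sd (in bp) as the error.
#'
#' Candidates are never pre-filtered: the mirror image of the true site
#' about each reference cut is a genuine candidate, and only the
#' accumulation of mass from several reference points resolves the
#' reflection ambiguity. With a single reference enzyme the two mirror
#' clusters are inherently indistinguishable and are both reported
#' (use `min_support = 1` to see them). A site closer than about half
#' `cluster_threshold` to a reference cut merges with its own mirror
#' about that cut and the estimate is pulled toward the cut by the
#' contaminating candidates; such near-coincident geometries are below
#' the resolution of fragment sizing.
#'
#' Clustering: candidates are split at circular gaps larger than
#' `cluster_threshold`, then refined by reassigning each candidate to
#' the nearest cluster centroid (circular distance) until convergence
#' (at most 100 iterations), which also settles clusters straddling the
#' antipode of another.
#'
#' @param obs A data.frame of fragment observations with columns
#'   `reference_enzyme`, `length_bp`, and optionally `length_sd_bp`
#'   (default 10, the typical agarose sizing accuracy) and
#'   `band_volume`.
#' @param map A [restriction_map()] containing every referenced enzyme.
#' @param cluster_threshold Circular gap (bp) separating clusters;
#'   default 15, about 1.5x the stated ~10 bp length accuracy.
#' @param min_support Minimum number of distinct reference enzymes a
#'   cluster needs to be reported (default 2).
#' @return A data.frame of class `cleavage_site_estimates` with columns
#'   `position`, `error_bp`, `n_support` (distinct enzymes),
#'   `n_candidates`, `enzymes` (comma-joined), sorted by support then
#'   candidate count, both decreasing. Zero rows (with a warning) if no
#'   cluster reaches `min_support`.
#' @examples
#' mc <- minicircle_sequence("336")
#' rmap <- restriction_map(mc, c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI"))
#' obs <- gen_fragment_observations(data.frame(position = 143, weight = 1),
#'                                  rmap, length_sd = 0, seed = 1)
#' triangulate_sites(obs, rmap)
#' @export
triangulate_sites <- function(obs, map, cluster_threshold = 15,
                              min_support = 2) {
  stopifnot(inherits(map, "restriction_map"))
  if (!is.data.frame(obs) || nrow(obs) < 1L ||
      !all(c("reference_enzyme", "length_bp") %in% names(obs)))
    stop("'obs' must be a data.frame with >= 1 row and columns ",
         "'reference_enzyme' and 'length_bp'", call. = FALSE)
  N <- map$sequence$length
  unknown <- setdiff(unique(obs$reference_enzyme), map$entries$enzyme)
  if (length(unknown) > 0L)
    stop("reference enzyme(s) not in map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(obs$length_bp <= 0 | obs$length_bp >= N))
    stop("'length_bp' must lie strictly between 0 and N", call. = FALSE)

  # expand: every observation x every cut of its reference enzyme x 2 signs
  cand <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
    enz <- obs$reference_enzyme[i]
    L <- obs$length_bp[i]
    r <- map$entries$position[map$entries$enzyme == enz]
    data.frame(enzyme = enz,
               position = as.numeric(wrap_pos(round(c(r + L, r - L)), N)))
  }))

  clusters <- cluster_circular(cand$position, N, cluster_threshold)
  est <- do.call(rbind, lapply(clusters, function(idx) {
    cm <- circular_mean_bp(cand$position[idx], N)
    enz <- sort(unique(cand$enzyme[idx]))
    data.frame(position = cm$mean, error_bp = cm$sd_bp,
               n_support = length(enz), n_candidates = length(idx),
               enzymes = paste(enz, collapse = ","))
  }))
  est <- est[est$n_support >= min_support, , drop = FALSE]
  if (nrow(est) == 0L)
    warning("no candidate cluster reached the minimum support of ",
            min_support, " distinct reference enzymes", call. = FALSE)
  est <- est[order(-est$n_support, -est$n_candidates, est$position), ,
             drop = FALSE]
  rownames(est) <- NULL
  class(est) <- c("cleavage_site_estimates", class(est))
  est
}

# gap-split initialisation + centroid reassignment on the circle
cluster_circular <- function(pos, N, threshold) {
  n <- length(pos)
  if (n == 1L) return(list(1L))
  ord <- order(pos)
  sorted <- pos[ord]
  gaps <- diff(c(sorted, sorted[1L] + N))  # gap i: sorted[i] -> next
  if (all(gaps <= threshold)) return(list(seq_len(n)))  # one wrap-around blob
  # start a new cluster after each large gap, walking from the largest gap
  start <- which.max(gaps) %% n + 1L
  idx <- c(seq(start, n), if (start > 1L) seq(1L, start - 1L))
  assign <- integer(n)
  cl <- 1L
  for (j in seq_len(n)) {
    i <- idx[j]
    assign[ord[i]] <- cl
    if (gaps[i] > threshold && j < n) cl <- cl + 1L
  }
  # refine: reassign to nearest circular centroid until stable
  for (iter in seq_len(100L)) {
    cent <- vapply(split(pos, assign),
                   function(p) circular_mean_bp(p, N)$mean, numeric(1L))
    d <- abs(outer(pos, cent, function(p, c) circ_delta(c, p, N)))
    new <- as.integer(names(cent))[apply(d, 1L, which.min)]
    if (identical(new, assign)) break
    assign <- new
  }
  unname(split(seq_len(n), assign))
}

#' Convert band volumes to molar site fractions
#'
#' Intercalating / surface stains report mass, so band volume is
#' proportional to molarity times fragment length. Dividing each volume
#' by its fragment length and normalising gives the molar fraction of
#' each species, the quantity cleavage-site preferences are expressed
#' in.
#'
#' @param band_volume Non-negative stain volumes (arbitrary units).
#' @param fragment_length Positive fragment lengths (bp), same length.
#' @return Numeric molar fractions summing to 1.
#' @examples
#' site_molar_fractions(c(1, 1), c(100, 300))  # 0.75, 0.25
#' @export
site_molar_fractions <- function(band_volume, fragment_length) {
  if (length(band_volume) != length(fragment_length))
    stop("'band_volume' and 'fragment_length' must have equal length",
         call. = FALSE)
  if (any(band_volume < 0)) stop("volumes must be >= 0", call. = FALSE)
  if (any(fragment_length <= 0)) stop("lengths must be > 0", call. = FALSE)
  moles <- band_volume / fragment_length
  tot <- sum(moles)
  if (tot == 0)
    stop("degenerate input: all band volumes are zero", call. = FALSE)
  moles / tot
}
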