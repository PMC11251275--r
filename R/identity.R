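#' Pairwise global-alignment identity between two protein sequences
#'
#' Aligns the two sequences globally (Needleman-Wunsch with affine gaps;
#' a gap of length L costs `gap_open + L * gap_extend`) and returns the
#' fraction of identical columns. The denominator is configurable because
#' cluster counts depend on it: `"alignment"` (default) divides by the full
#' alignment length including gap columns; `"shorter"` divides by the
#' shorter sequence's length (the convention of common heuristic
#' clustering tools).
#'
#' @param a,b Amino-acid strings (uppercase, non-empty).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring.
#' @param denominator `"alignment"` or `"shorter"`.
#' @return Identity fraction in \[0, 1\], with attributes `matches`,
#'   `align_length`, `score`.
#' @examples
#' pairwise_identity("AAAA", "AAAT") # 0.75
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -1,
                              denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  if (grepl("[^A-Z]", a) || grepl("[^A-Z]", b))
    stop("sequences must be uppercase letters", call. = FALSE)
  # canonical argument order makes the traceback (and hence the identity
  # under score ties) symmetric in (a, b)
  if (nchar(a) < nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  st <- nw_align_stats(a, b, match, mismatch, gap_open, gap_extend)
  den <- if (denominator == "alignment") st$align_length
         else min(nchar(a), nchar(b))
  out <- st$matches / den
  attr(out, "matches") <- st$matches
  attr(out, "align_length") <- st$align_length
  attr(out, "score") <- st$score
  out
}

as_sequence_set <- function(seqs) {
  if (inherits(seqs, "sequence_set")) return(seqs)
  if (is.data.frame(seqs)) {
    stopifnot(all(c("id", "residues") %in% names(seqs)))
    class(seqs) <- c("sequence_set", "data.frame")
    return(seqs)
  }
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(seqs))
    out <- data.frame(id = ids, residues = unname(seqs),
                      stringsAsFactors = FALSE)
    class(out) <- c("sequence_set", "data.frame")
    return(out)
  }
  stop("cannot interpret input as a sequence set", call. = FALSE)
}

#' Greedy centroid clustering at an identity threshold
#'
#' Processes sequences in descending length (ties broken by id) and
#' assigns each to the first existing centroid with identity at or above
#' `threshold`; otherwise the sequence founds a new cluster. Deterministic
#' for a given input set regardless of input order (the canonical
#' processing order is recomputed internally).
#'
#' @param seqs A `sequence_set` data.frame (columns `id`, `residues`), a
#'   named character vector, or the output of
#'   [simulate_sequence_family()].
#' @param threshold Identity threshold in (0, 1].
#' @param ... Passed to [pairwise_identity()].
#' @return An object of class `cluster_assignment`: data.frame with
#'   columns `member_id`, `centroid_id`, `identity`, plus attributes
#'   `threshold`, `centroids` (ids in founding order) and `settings`.
#' @export
greedy_cluster <- function(seqs, threshold, ...) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  s <- as_sequence_set(seqs)
  if (anyDuplicated(s$id)) stop("duplicate sequence ids", call. = FALSE)
  ord <- order(-nchar(s$residues), s$id)
  s <- s[ord, , drop = FALSE]

  centroids <- integer(0)        # row indices of centroids
  assign_to <- integer(nrow(s))  # centroid row index per member
  ident <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    hit <- 0L
    for (ci in centroids) {
      pid <- pairwise_identity(s$residues[i], s$residues[ci], ...)
      if (pid >= threshold) { hit <- ci; ident[i] <- as.numeric(pid); break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      assign_to[i] <- i
      ident[i] <- 1
    } else assign_to[i] <- hit
  }
  out <- data.frame(member_id = s$id, centroid_id = s$id[assign_to],
                    identity = ident, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "centroids") <- s$id[centroids]
  attr(out, "settings") <- list(...)
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Iterative representative selection over tagged subsets
#'
#' Emulates staged diversity coverage: each stage clusters the subset of
#' sequences carrying its tag at its own identity threshold and keeps the
#' cluster centroids; the representative set is the union of all stages'
#' centroids (representatives may overlap between stages and are
#' de-duplicated). A stage whose tag matches no sequence is skipped with a
#' warning.
#'
#' @param seqs A `sequence_set` data.frame; subset tags are taken from a
#'   `subset_tags` column (comma-separated labels) when present, else all
#'   sequences belong to every stage.
#' @param scheme Data.frame with columns `tag` and `threshold` (identity
#'   fractions), one row per stage, in order. Use tag `"all"` for a global
#'   stage.
#' @param ... Passed to [pairwise_identity()].
#' @return List with `representatives` (unique ids), `stages` (data.frame
#'   of per-stage tag, threshold, subset size, centroid count) and
#'   `assignments` (per-stage `cluster_assignment`s).
#' @export
iterative_select <- function(seqs, scheme, ...) {
  s <- as_sequence_set(seqs)
  stopifnot(all(c("tag", "threshold") %in% names(scheme)))
  if (any(scheme$threshold <= 0))
    stop("scheme thresholds must be positive", call. = FALSE)
  tags <- if ("subset_tags" %in% names(s)) {
    strsplit(s$subset_tags, ",", fixed = TRUE)
  } else rep(list(character(0)), nrow(s))

  reps <- character(0)
  assignments <- list()
  st <- vector("list", nrow(scheme))
  for (k in seq_len(nrow(scheme))) {
    tag <- scheme$tag[k]
    in_stage <- if (tag == "all") rep(TRUE, nrow(s)) else
      vapply(tags, function(tt) tag %in% tt, logical(1))
    if (!any(in_stage)) {
      warning("stage '", tag, "' matches no sequences; skipped",
              call. = FALSE)
      st[[k]] <- data.frame(tag = tag, threshold = scheme$threshold[k],
                            n_subset = 0L, n_centroids = 0L)
      next
    }
    ca <- greedy_cluster(s[in_stage, , drop = FALSE],
                         scheme$threshold[k], ...)
    cents <- attr(ca, "centroids")
    reps <- c(reps, cents)
    assignments[[paste0(tag, "@", scheme$threshold[k])]] <- ca
    st[[k]] <- data.frame(tag = tag, threshold = scheme$threshold[k],
                          n_subset = sum(in_stage),
                          n_centroids = length(cents))
  }
  list(representatives = unique(reps), stages = do.call(rbind, st),
       assignments = assignments)
}

#' Length-filter a sequence set
#'
#' Removes sequences outside a length range before clustering (the form I
#' large-subunit screen used 300-700 amino acids).
#'
#' @param seqs A `sequence_set` data.frame or named character vector.
#' @param min,max Inclusive length bounds (residues).
#' @return The filtered `sequence_set`.
#' @export
filter_sequence_length <- function(seqs, min = 300, max = 700) {
  s <- as_sequence_set(seqs)
  n <- nchar(s$residues)
  out <- s[n >= min & n <= max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return A `sequence_set` data.frame (`id`, `residues`).
#' @export
read_fasta_set <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  out <- data.frame(id = ids, residues = as.character(x),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("sequence_set", "data.frame")
  out
}

#' Write a sequence set to FASTA (wrapped at 60 columns)
#'
#' @param seqs A `sequence_set` data.frame or named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_set <- function(seqs, path) {
  s <- as_sequence_set(seqs)
  x <- Biostrings::AAStringSet(setNames(s$residues, s$id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
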