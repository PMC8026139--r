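#' Alignment scheme for percent-identity computation
#'
#' Pairwise global (Needleman-Wunsch) alignment chooses the path; identity
#' is then counted as identical columns over the full alignment length
#' including gap columns, the convention that yields single-digit identities
#' for unrelated proteins.
#'
#' @param substitution_matrix Scoring matrix name (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension Positive penalties (defaults 10 and 1).
#' @return A list of class `"identity_scheme"`.
#' @export
identity_scheme <- function(substitution_matrix = "BLOSUM62",
                            gap_opening = 10, gap_extension = 1) {
  structure(list(substitution_matrix = substitution_matrix,
                 gap_opening = gap_opening, gap_extension = gap_extension),
            class = "identity_scheme")
}

aligned_identity <- function(pattern_chars, subject_chars) {
  100 * sum(pattern_chars == subject_chars & pattern_chars != "-") /
    length(pattern_chars)
}

#' Percent identity between two protein sequences
#'
#' @param a,b Amino-acid strings (20-letter alphabet, `X` allowed).
#' @param scheme An [identity_scheme()].
#' @return Percent identity in \[0, 100\].
#' @examples
#' pairwise_identity("ACDEFG", "ACDEYG") # 83.33
#' @export
pairwise_identity <- function(a, b, scheme = identity_scheme()) {
  if (!nzchar(a) || !nzchar(b)) rlang::abort("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_opening, gapExtension = scheme$gap_extension)
  aligned_identity(strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
                   strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]])
}

#' Pairwise percent-identity matrix for a protein panel
#'
#' All unordered pairs are aligned; the matrix is symmetric by construction
#' with a diagonal of exactly 100.
#'
#' @param records Tibble with columns `id` (unique) and `sequence`.
#' @param scheme An [identity_scheme()].
#' @return A symmetric numeric matrix with `id` dimnames, class
#'   `"identity_matrix"`.
#' @export
identity_matrix <- function(records, scheme = identity_scheme()) {
  if (nrow(records) < 2) rlang::abort("need at least 2 records")
  if (anyDuplicated(records$id)) {
    rlang::abort(sprintf("duplicate ids: %s",
                         paste(unique(records$id[duplicated(records$id)]), collapse = ", ")))
  }
  n <- nrow(records)
  ss <- Biostrings::AAStringSet(records$sequence)
  M <- diag(100, n)
  for (i in seq_len(n - 1)) {
    al <- Biostrings::pairwiseAlignment(
      ss[rep(i, n - i)], ss[(i + 1):n], type = "global",
      substitutionMatrix = scheme$substitution_matrix,
      gapOpening = scheme$gap_opening, gapExtension = scheme$gap_extension)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")
    vals <- mapply(aligned_identity, pa, sa)
    M[i, (i + 1):n] <- vals
    M[(i + 1):n, i] <- vals
  }
  dimnames(M) <- list(records$id, records$id)
  structure(M, class = c("identity_matrix", "matrix", "array"))
}

#' Median pairwise identity over a panel subset
#'
#' Median of the off-diagonal upper-triangle identities restricted to the
#' subset; with an even pair count, the mean of the central pair.
#'
#' @param m An [identity_matrix()].
#' @param subset Character vector of ids (default: all).
#' @return Median percent identity.
#' @export
median_identity <- function(m, subset = NULL) {
  ids <- rownames(m)
  subset <- subset %||% ids
  missing <- setdiff(subset, ids)
  if (length(missing) > 0) {
    rlang::abort(sprintf("unknown id(s): %s", paste(missing, collapse = ", ")))
  }
  if (length(subset) < 2) rlang::abort("subset must contain at least 2 ids")
  mm <- unclass(m)[subset, subset, drop = FALSE]
  stats::median(mm[upper.tri(mm)])
}

#' Summary counts of an enzyme activity screen
#'
#' @param records Tibble with columns `id` and logical `active` (no
#'   missing values).
#' @return One-row tibble `n_tested`, `n_active`, `fraction_active`
#'   (3 decimals; `NA` for an empty panel).
#' @export
screen_summary <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(n_tested = 0L, n_active = 0L, fraction_active = NA_real_))
  }
  unknown <- records$id[is.na(records$active)]
  if (length(unknown) > 0) {
    rlang::abort(sprintf("activity unknown for: %s", paste(unknown, collapse = ", ")))
  }
  tibble::tibble(
    n_tested = nrow(records),
    n_active = sum(records$active),
    fraction_active = round(sum(records$active) / nrow(records), 3)
  )
}

#' Read a protein FASTA (plus optional activity metadata CSV)
#'
#' @param fasta_path FASTA file; ids must be unique.
#' @param metadata_path Optional CSV with columns `id`, `active`, and
#'   optionally `ec_class`.
#' @return Tibble `id`, `sequence`, `active`, `ec_class`.
#' @export
read_protein_panel <- function(fasta_path, metadata_path = NULL) {
  ss <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) rlang::abort("duplicate FASTA ids")
  out <- tibble::tibble(id = ids, sequence = unname(as.character(ss)),
                        active = NA, ec_class = NA_character_)
  if (!is.null(metadata_path)) {
    meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    out$active <- as.logical(meta$active[match(out$id, meta$id)])
    if ("ec_class" %in% names(meta)) {
      out$ec_class <- meta$ec_class[match(out$id, meta$id)]
    }
  }
  out
}

#' Write a protein panel as FASTA
#' @param records Tibble with `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  writeLines(paste0(">", records$id, "\n", records$sequence), path)
  invisible(path)
}

#' Export an identity matrix as a PHYLIP-style distance matrix
#'
#' Distances are `(100 - identity) / 100`, suitable for external tree
#' tools.
#'
#' @param m An [identity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  ids <- rownames(m)
  d <- (100 - unclass(m)) / 100
  diag(d) <- 0
  lines <- c(sprintf("%5d", length(ids)),
             vapply(seq_along(ids), function(i) {
               paste0(formatC(ids[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
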