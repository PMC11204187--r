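#' Discrete character matrix
#'
#' Container for a taxa-by-characters table of discrete morphological states.
#' States are single digits 0--9; missing cells (coded `?` in the file
#' dialects) are stored as `NA`. Taxon labels are whitespace-normalized and
#' must be unique.
#'
#' @param states integer (or digit-character) matrix, taxa in rows. `NA` marks
#'   a missing cell. Row names are taken as taxon labels unless `taxa` is
#'   given.
#' @param taxa character vector of taxon labels, one per row.
#' @param char_defs optional data frame of per-character metadata with at
#'   least columns `index` and `description`.
#' @return an object of class `char_matrix` with elements `states` (integer
#'   matrix with `NA` for missing), `taxa`, `n_chars` and `char_defs`.
#' @export
char_matrix <- function(states, taxa = rownames(states), char_defs = NULL) {
  if (is.character(states)) {
    st <- suppressWarnings(matrix(as.integer(states), nrow = nrow(states)))
    bad <- !is.na(states) & states != "?" & is.na(st)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("state error: unknown state symbol '%s' for taxon '%s', character %d",
                   states[bad][1], taxa[idx[1]], idx[2]))
    }
    st[states == "?"] <- NA_integer_
    states <- st
  }
  storage.mode(states) <- "integer"
  if (is.null(taxa)) stop("taxon labels required")
  taxa <- squish(as.character(taxa))
  if (length(taxa) != nrow(states)) stop("dimension error: one label per row required")
  if (any(taxa == "")) stop("taxon labels must be non-empty")
  if (anyDuplicated(taxa)) stop(sprintf("taxon labels not unique: '%s'",
                                        taxa[duplicated(taxa)][1]))
  if (nrow(states) && any(!is.na(states))) {
    rng <- range(states, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > 9L)
      stop("state error: states must be single digits 0-9")
  }
  rownames(states) <- taxa
  if (is.null(colnames(states)))
    colnames(states) <- sprintf("c%02d", seq_len(ncol(states)))
  structure(list(states = states, taxa = taxa, n_chars = ncol(states),
                 char_defs = char_defs),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters, %d missing cells\n",
              length(x$taxa), x$n_chars, sum(is.na(x$states))))
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

n_taxa <- function(m) length(m$taxa)

#' Check a matrix for analytically suspect features
#'
#' Reports non-fatal findings: characters that are constant or entirely
#' missing (parsimony-uninformative) and pairs of taxa with identical rows.
#' Structural violations (ragged rows, bad states, duplicate labels) are
#' rejected at construction time instead.
#'
#' @param matrix a [char_matrix()].
#' @return data frame with columns `type` and `message`; zero rows when
#'   nothing is flagged.
#' @export
validate_matrix <- function(matrix) {
  st <- matrix$states
  findings <- list()
  for (j in seq_len(ncol(st))) {
    col <- st[, j]
    obs <- col[!is.na(col)]
    if (!length(obs)) {
      findings[[length(findings) + 1L]] <-
        data.frame(type = "all_missing",
                   message = sprintf("character %d uninformative: all missing", j))
    } else if (length(unique(obs)) == 1L) {
      findings[[length(findings) + 1L]] <-
        data.frame(type = "constant",
                   message = sprintf("character %d uninformative: constant", j))
    }
  }
  key <- apply(st, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  dup <- which(duplicated(key))
  for (i in dup) {
    first <- matrix$taxa[match(key[i], key)]
    findings[[length(findings) + 1L]] <-
      data.frame(type = "duplicate_row",
                 message = sprintf("taxa '%s' and '%s' have identical rows",
                                   first, matrix$taxa[i]))
  }
  if (!length(findings))
    data.frame(type = character(0), message = character(0))
  else do.call(rbind, findings)
}

#' Checksum of a character matrix
#'
#' MD5 digest of the canonical CSV serialization; used to pin the bundled
#' matrix transcription.
#'
#' @param matrix a [char_matrix()].
#' @return hex string.
#' @export
matrix_checksum <- function(matrix) {
  txt <- write_matrix(matrix, dialect = "csv")
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(txt, f, eos = NULL)
  unname(tools::md5sum(f))
}
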