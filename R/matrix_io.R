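#' Parse a character matrix from text
#'
#' Reads a discrete matrix from one of three dialects:
#' \describe{
#'   \item{`nexus`}{a minimal `DATA`/`CHARACTERS` block (`DIMENSIONS`,
#'     `FORMAT ... MISSING=?`, `MATRIX`); taxon labels use underscores for
#'     spaces.}
#'   \item{`tnt`}{an `xread` block (`xread 'title' nchar ntax` followed by
#'     taxon/state rows).}
#'   \item{`csv`}{header row of character ids, first column the taxon label.}
#' }
#' `?` is the only missing symbol; states are single digits.
#'
#' @param text character scalar (may contain newlines) or vector of lines.
#' @param dialect one of `"nexus"`, `"tnt"`, `"csv"`.
#' @return a [char_matrix()].
#' @export
parse_matrix <- function(text, dialect = c("nexus", "tnt", "csv")) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  switch(dialect,
         nexus = parse_nexus_matrix(lines),
         tnt   = parse_tnt_matrix(lines),
         csv   = parse_csv_matrix(lines))
}

split_states <- function(str, taxon, line_no) {
  cells <- strsplit(gsub("\\s+", "", str), "")[[1]]
  bad <- !(cells %in% c(as.character(0:9), "?"))
  if (any(bad))
    stop(sprintf("state error (line %d): unknown state symbol '%s' for taxon '%s', character %d",
                 line_no, cells[bad][1], taxon, which(bad)[1]))
  cells
}

assemble_rows <- function(labels, rows, lines_at) {
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L) {
    off <- which(lens != lens[1])[1]
    stop(sprintf("dimension error (line %d): taxon '%s' has %d cells, expected %d",
                 lines_at[off], labels[off], lens[off], lens[1]))
  }
  m <- do.call(rbind, rows)
  char_matrix(m, taxa = labels)
}

parse_nexus_matrix <- function(lines) {
  up <- toupper(lines)
  mstart <- grep("^\\s*MATRIX\\s*$", up)
  if (!length(mstart)) stop("parse error: no MATRIX statement found (nexus)")
  dimln <- grep("DIMENSIONS", up)
  ntax <- nchar_decl <- NA_integer_
  if (length(dimln)) {
    d <- up[dimln[1]]
    ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", d))
    nchar_decl <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", d))
  }
  labels <- character(0); rows <- list(); at <- integer(0)
  for (i in seq(mstart[1] + 1L, length(lines))) {
    ln <- squish(lines[i])
    if (ln == "") next
    if (ln == ";" || grepl("^END", toupper(ln))) break
    if (grepl(";\\s*$", ln)) ln <- squish(sub(";\\s*$", "", ln))
    if (ln == "") break
    sp <- regexpr(" ", ln)
    if (sp < 0) stop(sprintf("parse error (line %d, col %d): expected 'label states'", i, nchar(ln)))
    lab <- tip_to_label(substr(ln, 1, sp - 1))
    labels <- c(labels, lab); at <- c(at, i)
    rows[[length(rows) + 1L]] <- split_states(substr(ln, sp + 1, nchar(ln)), lab, i)
  }
  m <- assemble_rows(labels, rows, at)
  if (!is.na(ntax) && ntax != length(m$taxa))
    stop(sprintf("dimension error: DIMENSIONS declares NTAX=%d but %d rows read", ntax, length(m$taxa)))
  if (!is.na(nchar_decl) && nchar_decl != m$n_chars)
    stop(sprintf("dimension error: DIMENSIONS declares NCHAR=%d but %d columns read", nchar_decl, m$n_chars))
  m
}

parse_tnt_matrix <- function(lines) {
  hstart <- grep("^\\s*xread", lines, ignore.case = TRUE)
  if (!length(hstart)) stop("parse error: no xread header found (tnt)")
  i <- hstart[1]
  # header: optional quoted title, then "nchar ntax" (possibly on later lines)
  nums <- NULL
  while (i <= length(lines)) {
    ln <- squish(gsub("'[^']*'", "", sub("^\\s*xread", "", lines[i], ignore.case = TRUE)))
    if (grepl("^\\d+\\s+\\d+$", ln)) { nums <- as.integer(strsplit(ln, " ")[[1]]); break }
    i <- i + 1L
    if (i > length(lines) || i > hstart[1] + 4L)
      stop("parse error: xread dimensions 'nchar ntax' not found (tnt)")
  }
  labels <- character(0); rows <- list(); at <- integer(0)
  for (k in seq(i + 1L, length(lines))) {
    ln <- squish(lines[k])
    if (ln == "") next
    if (ln == ";" || grepl("^proc", ln, ignore.case = TRUE)) break
    if (grepl(";\\s*$", ln)) ln <- squish(sub(";\\s*$", "", ln))
    if (ln == "") break
    sp <- regexpr(" ", ln)
    if (sp < 0) stop(sprintf("parse error (line %d, col %d): expected 'label states'", k, nchar(ln)))
    lab <- tip_to_label(substr(ln, 1, sp - 1))
    labels <- c(labels, lab); at <- c(at, k)
    rows[[length(rows) + 1L]] <- split_states(substr(ln, sp + 1, nchar(ln)), lab, k)
  }
  m <- assemble_rows(labels, rows, at)
  if (!is.null(nums)) {
    if (nums[1] != m$n_chars)
      stop(sprintf("dimension error: xread declares %d characters but %d read", nums[1], m$n_chars))
    if (nums[2] != length(m$taxa))
      stop(sprintf("dimension error: xread declares %d taxa but %d read", nums[2], length(m$taxa)))
  }
  m
}

parse_csv_matrix <- function(lines) {
  lines <- lines[squish(lines) != ""]
  if (!length(lines)) stop("parse error: empty csv input")
  has_header <- grepl("^\\s*(taxon|Taxon)", lines[1]) ||
    !grepl("^[^,]*,[0-9?](,|$)", lines[1])
  body <- if (has_header && length(lines) > 1L &&
              all(grepl(",", lines[-1], fixed = TRUE))) lines[-1] else lines
  line0 <- if (identical(body, lines)) 0L else 1L
  labels <- character(0); rows <- list(); at <- integer(0)
  for (k in seq_along(body)) {
    parts <- strsplit(body[k], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop(sprintf("parse error (line %d): expected 'label,states...'", k + line0))
    lab <- squish(parts[1])
    labels <- c(labels, lab); at <- c(at, k + line0)
    rows[[length(rows) + 1L]] <- split_states(paste(parts[-1], collapse = ""), lab, k + line0)
  }
  assemble_rows(labels, rows, at)
}

#' Write a character matrix to text
#'
#' Emits text that [parse_matrix()] reads back to a cell-for-cell identical
#' matrix. In the `nexus` and `tnt` dialects spaces in taxon labels become
#' underscores (the conversion is reversed on parsing), so labels that
#' themselves contain underscores, or characters reserved by the dialect, are
#' rejected rather than emitted unparseably.
#'
#' @param matrix a [char_matrix()].
#' @param dialect one of `"nexus"`, `"tnt"`, `"csv"`.
#' @return a single string.
#' @export
write_matrix <- function(matrix, dialect = c("nexus", "tnt", "csv")) {
  dialect <- match.arg(dialect)
  st <- matrix$states
  cells <- matrix(ifelse(is.na(st), "?", as.character(st)), nrow = nrow(st))
  rowstr <- apply(cells, 1, paste, collapse = "")
  taxa <- matrix$taxa
  if (dialect %in% c("nexus", "tnt")) {
    bad <- grepl("_", taxa, fixed = TRUE) | grepl("[;()'\\]\\[]", taxa)
    if (any(bad))
      stop(sprintf("label error: '%s' contains characters reserved in the %s dialect",
                   taxa[bad][1], dialect))
    labs <- label_to_tip(taxa)
  } else {
    bad <- grepl("[,\"\n]", taxa)
    if (any(bad))
      stop(sprintf("label error: '%s' contains characters reserved in the csv dialect",
                   taxa[bad][1]))
    labs <- taxa
  }
  w <- max(nchar(labs))
  body <- paste(sprintf("%-*s %s", w, labs, rowstr), collapse = "\n")
  syms <- sort(unique(st[!is.na(st)]))
  if (!length(syms)) syms <- 0L
  switch(dialect,
    nexus = paste0("#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=", nrow(st),
                   " NCHAR=", ncol(st), ";\nFORMAT SYMBOLS=\"",
                   paste(syms, collapse = ""), "\" MISSING=?;\nMATRIX\n",
                   body, "\n;\nEND;\n"),
    tnt = paste0("xread\n'", "exported matrix", "'\n", ncol(st), " ", nrow(st),
                 "\n", body, "\n;\n"),
    csv = paste0("taxon,", paste(colnames(st), collapse = ","), "\n",
                 paste(taxa, apply(cells, 1, paste, collapse = ","), sep = ",",
                       collapse = "\n"), "\n"))
}

extdata <- function(file) {
  system.file("extdata", file, package = "morphparsimony", mustWork = TRUE)
}

#' The bundled hagloid wing-venation matrix
#'
#' The 13-taxon, 24-character forewing matrix (states 0--3, `?` missing) of
#' Cyrtophyllitinae sensu lato plus two outgroups, with per-character
#' metadata attached. Taxon spellings are kept exactly as published
#' (including "Vitmoilus gigantus sp. n."); [taxon_metadata()] carries the
#' corrected-spelling alias.
#'
#' @return a [char_matrix()] with 13 taxa and 24 characters.
#' @export
bundled_matrix <- function() {
  m <- parse_matrix(readLines(extdata("table3.nex")), dialect = "nexus")
  m$char_defs <- read.csv(extdata("table2_characters.csv"), stringsAsFactors = FALSE)
  m
}

#' Taxon metadata for the bundled matrix
#'
#' Geological age codes (J1 Early Jurassic, J2 Middle Jurassic, J3 Late
#' Jurassic, K1 Early Cretaceous), analysis roles (ingroup / outgroup /
#' excluded) and spelling aliases for the species of the study group.
#'
#' @return data frame with columns `taxon`, `age_code`, `role`, `alias`.
#' @export
taxon_metadata <- function() {
  md <- read.csv(extdata("table1_taxa.csv"), stringsAsFactors = FALSE,
                 na.strings = "")
  stopifnot(all(md$role %in% c("ingroup", "outgroup", "excluded")))
  md
}

#' Named taxon groups used by the clade queries
#'
#' @return named list of character vectors of taxon labels.
#' @export
named_groups <- function() {
  g <- read.csv(extdata("groups.csv"), stringsAsFactors = FALSE)
  split(g$member, g$group)
}
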