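#' phytab: the four-column multi-gene data format
#'
#' A phytab dataset is an ordered table of sequence records with four
#' tab-delimited columns and no header row:
#' \enumerate{
#'   \item \code{species} -- taxon label,
#'   \item \code{partition} -- data partition (gene family) label,
#'   \item \code{uid} -- unique identifier (e.g. an accession); may be empty,
#'   \item \code{sequence} -- sequence or morphological character data
#'     (gaps \code{-} and missing \code{?} permitted).
#' }
#' Keeping every partition in one flat file lets each gene family be
#' extracted and analyzed independently (and in parallel), while the same
#' file also feeds supermatrix concatenation.
#'
#' @param species,partition,uid,sequence character vectors of equal length.
#' @param provenance free-text note on where the records came from.
#' @return A data.frame of class \code{"phytab"} with the four columns above
#'   and a \code{"provenance"} attribute.
#' @examples
#' d <- phytab("Homo", "opsin", "U1", "ATGC")
#' write_phytab(d)
#' @export
phytab <- function(species = character(), partition = character(),
                   uid = character(), sequence = character(),
                   provenance = "in-memory") {
  d <- data.frame(species = as.character(species),
                  partition = as.character(partition),
                  uid = as.character(uid),
                  sequence = as.character(sequence),
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  class(d) <- c("phytab", "data.frame")
  attr(d, "provenance") <- provenance
  validate_phytab(d)
  d
}

#' Validate a phytab dataset
#'
#' Checks the phytab invariants: four character columns; species and
#' partition labels non-empty and free of tabs/newlines; sequences non-empty.
#'
#' @param d a phytab dataset (or plain data.frame with the four columns).
#' @return \code{d}, invisibly, if valid; otherwise an error is raised.
#' @export
validate_phytab <- function(d) {
  cols <- c("species", "partition", "uid", "sequence")
  if (!is.data.frame(d) || !all(cols %in% names(d)))
    stop("not a phytab dataset: need columns ", paste(cols, collapse = ", "))
  if (nrow(d) == 0) return(invisible(d))
  for (col in c("species", "partition")) {
    v <- d[[col]]
    bad <- which(is.na(v) | v == "")
    if (length(bad))
      stop("empty ", col, " in record(s) ", paste(utils::head(bad, 5), collapse = ", "))
    bad <- which(grepl("[\t\n\r]", v))
    if (length(bad))
      stop(col, " contains tab/newline in record(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(is.na(d$sequence) | d$sequence == "")
  if (length(bad))
    stop("empty sequence in record(s) ", paste(utils::head(bad, 5), collapse = ", "))
  invisible(d)
}

#' Parse phytab text
#'
#' Reads tab-delimited phytab content: one record per non-blank line, at
#' least four fields per line (extra fields are ignored with a warning,
#' so annotated phytab files with appended columns still parse). A
#' \code{"."} in the uid column is the empty-uid sentinel and is read back
#' as the empty string.
#'
#' @param text phytab content as a single string or character vector of lines.
#' @param provenance free-text source note stored on the result.
#' @return A \code{phytab} dataset; record order follows file order.
#' @seealso [write_phytab()], [read_phytab()]
#' @export
parse_phytab <- function(text, provenance = "parsed text") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  keep <- which(!grepl("^\\s*$", lines))
  if (!length(keep))
    return(phytab(provenance = provenance))
  # sentinel keeps trailing empty fields (strsplit drops them otherwise)
  fields <- lapply(strsplit(paste0(lines[keep], "\t\x01"), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("phytab parse error: line(s) ",
         paste(keep[nf < 4L], collapse = ", "), " have fewer than 4 fields")
  if (any(nf > 4L))
    warning("ignoring extra fields on line(s) ",
            paste(keep[nf > 4L], collapse = ", "))
  m <- t(vapply(fields, function(f) f[1:4], character(4)))
  uid <- ifelse(m[, 3] == ".", "", m[, 3])
  phytab(m[, 1], m[, 2], uid, m[, 4], provenance = provenance)
}

#' @rdname parse_phytab
#' @param path path to a phytab file.
#' @export
read_phytab <- function(path) {
  parse_phytab(readLines(path, warn = FALSE), provenance = path)
}

#' Write a phytab dataset
#'
#' Serializes to tab-delimited text, four columns, no header, LF line
#' endings. Empty uids are written as the \code{"."} sentinel so the column
#' count stays four. \code{parse_phytab(write_phytab(d))} reproduces
#' \code{d} record-for-record.
#'
#' @param d a phytab dataset.
#' @param path optional file path; when \code{NULL} the text is returned.
#' @return The phytab text (invisibly when written to \code{path}).
#' @export
write_phytab <- function(d, path = NULL) {
  validate_phytab(d)
  if (nrow(d) == 0) {
    txt <- ""
  } else {
    uid <- ifelse(d$uid == "", ".", d$uid)
    txt <- paste0(paste(d$species, d$partition, uid, d$sequence, sep = "\t"),
                  "\n", collapse = "")
  }
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, sep = "\n")
  invisible(txt)
}

#' @export
print.phytab <- function(x, ...) {
  cat("phytab dataset: ", nrow(x), " records, ",
      length(unique(x$partition)), " partition(s), ",
      length(unique(x$species)), " species\n", sep = "")
  cat("provenance:", attr(x, "provenance") %||% "unknown", "\n")
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x), 6)
    show$sequence <- ifelse(nchar(show$sequence) > 30,
                            paste0(substr(show$sequence, 1, 30), "..."),
                            show$sequence)
    print(show)
    if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more records\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.data.frame.phytab <- function(x, ...) {
  data.frame(species = x$species, partition = x$partition, uid = x$uid,
             sequence = x$sequence, stringsAsFactors = FALSE)
}

# ---- FASTA interchange -----------------------------------------------------

#' Read FASTA content into a named character vector
#'
#' Accepts a file path or raw FASTA text; interleaved (multi-line) sequence
#' bodies are joined. Parsing is delegated to Biostrings.
#'
#' @param fasta FASTA content (string containing \code{>}) or a file path.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(fasta) {
  path <- fasta_as_path(fasta)
  if (length(readLines(path, warn = FALSE)) == 0L)
    return(stats::setNames(character(), character()))
  first <- grep("^\\s*$", readLines(path, warn = FALSE), invert = TRUE, value = TRUE)[1]
  if (is.na(first) || !startsWith(first, ">"))
    stop("malformed FASTA: sequence data before first '>' header")
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), names(set))
}

fasta_as_path <- function(fasta) {
  if (length(fasta) == 1L && !grepl("[>\n]", fasta) && file.exists(fasta))
    return(fasta)
  tf <- tempfile(fileext = ".fasta")
  writeLines(if (length(fasta) == 1L) strsplit(fasta, "\n")[[1]] else fasta, tf)
  tf
}

#' Convert FASTA to phytab
#'
#' Two header interpretations are supported. In \code{"first-token-uid"}
#' mode every record receives the supplied \code{species} and
#' \code{partition}, and the uid is the first whitespace-delimited token of
#' the header -- the usual case of a FASTA file holding one gene family from
#' one species. In \code{"delimited"} mode the header itself carries
#' species, partition and uid joined by \code{delimiter}.
#'
#' @param fasta FASTA content or file path (interleaved bodies accepted).
#' @param species,partition labels applied in \code{first-token-uid} mode.
#' @param header_mode \code{"first-token-uid"} or \code{"delimited"}.
#' @param delimiter header field separator for \code{delimited} mode.
#' @return A \code{phytab} dataset, in FASTA record order.
#' @examples
#' fasta_to_phytab(">seq1\nAT\nGC\n", species = "Homo", partition = "opsin")
#' @export
fasta_to_phytab <- function(fasta, species = NULL, partition = NULL,
                            header_mode = c("first-token-uid", "delimited"),
                            delimiter = "|") {
  header_mode <- match.arg(header_mode)
  seqs <- read_fasta(fasta)
  if (!length(seqs)) return(phytab(provenance = "fasta"))
  headers <- names(seqs)
  if (header_mode == "first-token-uid") {
    if (is.null(species) || is.null(partition))
      stop("first-token-uid mode needs species and partition labels")
    uid <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
    phytab(rep(species, length(seqs)), rep(partition, length(seqs)),
           uid, unname(seqs), provenance = "fasta")
  } else {
    parts <- strsplit(headers, delimiter, fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad))
      stop("delimited header does not have 3 '", delimiter, "'-separated ",
           "fields: ", headers[bad[1]])
    m <- t(vapply(parts, identity, character(3)))
    phytab(m[, 1], m[, 2], ifelse(m[, 3] == ".", "", m[, 3]),
           unname(seqs), provenance = "fasta")
  }
}

#' Convert phytab to FASTA
#'
#' Emits sequential (non-interleaved) FASTA with headers
#' \code{species<delim>partition<delim>uid}, the inverse of
#' [fasta_to_phytab()] in delimited mode. Empty uids use the \code{"."}
#' sentinel in the header.
#'
#' @param d a phytab dataset.
#' @param partition_filter optional partition label; only matching records
#'   are emitted (no match gives empty output with a warning).
#' @param delimiter header field separator.
#' @param path optional output file.
#' @return FASTA text (invisibly when written to \code{path}).
#' @export
phytab_to_fasta <- function(d, partition_filter = NULL, delimiter = "|",
                            path = NULL) {
  validate_phytab(d)
  if (!is.null(partition_filter)) {
    d <- d[d$partition %in% partition_filter, , drop = FALSE]
    if (nrow(d) == 0)
      warning("partition_filter matched no records; empty FASTA output")
  }
  txt <- if (nrow(d) == 0) "" else
    paste0(">", d$species, delimiter, d$partition, delimiter,
           ifelse(d$uid == "", ".", d$uid), "\n", d$sequence, "\n",
           collapse = "")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

# ---- TNT xread -------------------------------------------------------------

#' Convert a minimal TNT xread matrix to phytab
#'
#' Parses the minimal TNT dialect used for morphological matrices: an
#' \code{xread} keyword, an optional quoted title, \code{nchar} and
#' \code{ntax}, then one \code{taxon statestring} line per taxon. Each taxon
#' becomes one phytab record (species = uid = taxon name). Polymorphic
#' states like \code{[01]} are outside the minimal dialect and rejected.
#'
#' @param tnt TNT content as a string, character vector of lines, or path.
#' @param partition partition label for the resulting records.
#' @return A \code{phytab} dataset with one record per taxon.
#' @export
tnt_to_phytab <- function(tnt, partition = "morphology") {
  lines <- if (length(tnt) == 1L && !grepl("\n", tnt) && file.exists(tnt))
    readLines(tnt, warn = FALSE)
  else if (length(tnt) == 1L) strsplit(tnt, "\n", fixed = TRUE)[[1]]
  else tnt
  txt <- paste(lines, collapse = "\n")
  if (!grepl("\\bxread\\b", txt))
    stop("TNT parse error: no 'xread' keyword found")
  body <- sub(".*\\bxread\\b", "", txt)
  body <- gsub("'[^']*'", " ", body)          # quoted title
  body <- sub(";.*$", "", body)               # stop at terminating semicolon
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  toks <- toks[toks != ""]
  if (length(toks) < 2 || anyNA(suppressWarnings(as.integer(toks[1:2]))))
    stop("TNT parse error: expected 'nchar ntax' after xread")
  nchar_ <- as.integer(toks[1]); ntax <- as.integer(toks[2])
  toks <- toks[-(1:2)]
  if (ntax == 0L) {
    warning("TNT matrix declares ntax=0; empty dataset")
    return(phytab(provenance = "tnt"))
  }
  if (length(toks) != 2L * ntax)
    stop("TNT parse error: expected ", ntax,
         " 'taxon statestring' pairs, found ", length(toks) %/% 2L)
  taxa <- toks[seq(1, length(toks), by = 2)]
  states <- toks[seq(2, length(toks), by = 2)]
  if (any(grepl("\\[", states)))
    stop("polymorphic states like [01] are not supported by the minimal ",
         "xread dialect (taxon ", taxa[grep("\\[", states)[1]], ")")
  badlen <- which(nchar(states) != nchar_)
  if (length(badlen))
    stop("state string length != nchar (", nchar_, ") for taxon ",
         taxa[badlen[1]], " (length ", nchar(states[badlen[1]]), ")")
  phytab(taxa, rep(partition, ntax), taxa, states, provenance = "tnt")
}

# ---- record-level manipulation --------------------------------------------

#' Find and remove duplicate phytab records
#'
#' Groups records by the chosen key and reports every key occurring more
#' than once, with the record line numbers involved. The deduplicated
#' dataset keeps the first occurrence of each key, in input order. The
#' default key, species+partition, is the pair that collides in downstream
#' supermatrix rows.
#'
#' @param d a phytab dataset.
#' @param key \code{"species+partition"}, \code{"uid"}, or \code{"sequence"}.
#' @return list with \code{report} (data.frame: key, n, lines) and
#'   \code{dataset} (deduplicated phytab).
#' @export
find_duplicates <- function(d, key = c("species+partition", "uid", "sequence")) {
  key <- match.arg(key)
  validate_phytab(d)
  kv <- switch(key,
               "species+partition" = paste(d$species, d$partition, sep = "\t"),
               uid = d$uid,
               sequence = d$sequence)
  idx <- split(seq_len(nrow(d)), factor(kv, levels = unique(kv)))
  dup <- idx[lengths(idx) > 1L]
  report <- data.frame(
    key = if (length(dup)) gsub("\t", "|", names(dup)) else character(),
    n = if (length(dup)) lengths(dup) else integer(),
    lines = if (length(dup))
      vapply(dup, function(i) paste(i, collapse = ","), character(1))
    else character(),
    row.names = NULL, stringsAsFactors = FALSE)
  keep <- sort(vapply(idx, `[`, integer(1), 1L))
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(d)
  attr(out, "provenance") <- attr(d, "provenance")
  list(report = report, dataset = out)
}

#' Filter phytab records by a label list
#'
#' Keeps or removes records whose \code{field} value appears in
#' \code{names}, preserving input order. Listed names absent from the
#' dataset are reported with a warning. Keep-mode and remove-mode with the
#' same list partition the dataset.
#'
#' @param d a phytab dataset.
#' @param names character vector of labels (or path to a one-per-line list).
#' @param field \code{"species"}, \code{"partition"}, or \code{"uid"}.
#' @param mode \code{"keep"} or \code{"remove"}.
#' @return The filtered \code{phytab} dataset.
#' @export
prune_records <- function(d, names, field = c("species", "partition", "uid"),
                          mode = c("keep", "remove")) {
  field <- match.arg(field); mode <- match.arg(mode)
  validate_phytab(d)
  if (!length(names)) stop("names must be non-empty")
  missing <- setdiff(names, d[[field]])
  if (length(missing))
    warning("name(s) not present in dataset ", field, ": ",
            paste(missing, collapse = ", "))
  hit <- d[[field]] %in% names
  out <- d[if (mode == "keep") hit else !hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(d)
  attr(out, "provenance") <- attr(d, "provenance")
  out
}

#' Read a one-label-per-line species list
#' @param path file path.
#' @return character vector of labels (blank lines dropped).
#' @export
read_species_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[x != ""]
}
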