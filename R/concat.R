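# Supermatrix concatenation: coverage filtering, partition schemes,
# model assignment and occupancy reporting.

#' Per-partition aligned lengths of a phytab dataset
#'
#' Each partition must be internally aligned (uniform sequence length);
#' a partition violating this raises an error naming it.
#'
#' @param d a phytab dataset.
#' @return named integer vector, partition -> aligned length, in order of
#'   first appearance.
#' @export
partition_lengths <- function(d) {
  validate_phytab(d)
  parts <- unique(d$partition)
  out <- vapply(parts, function(p) {
    len <- unique(nchar(d$sequence[d$partition == p]))
    if (length(len) > 1L)
      stop("partition '", p, "' is not aligned: sequence lengths ",
           paste(sort(len), collapse = ", "))
    len
  }, integer(1))
  stats::setNames(out, parts)
}

#' Coverage-filter a phytab dataset before concatenation
#'
#' Applies, in order: (i) an optional species-list restriction; (ii) removal
#' of partitions whose aligned length is below \code{min_aligned_length};
#' (iii) iteration to a fixed point of two occupancy rules -- partitions
#' represented by fewer than \code{min_species_per_gene} species are
#' dropped, then species retaining fewer than \code{min_genes_per_species}
#' partitions are dropped -- repeated until nothing changes. The iteration
#' matters because removing a sparse gene can push a species below its
#' minimum (and vice versa); the log records every removal with its reason
#' and round.
#'
#' @param d a phytab dataset (each partition aligned).
#' @param min_genes_per_species minimum partitions a species must retain.
#' @param min_species_per_gene minimum species a partition must retain.
#' @param min_aligned_length minimum aligned partition length.
#' @param species_list optional character vector restricting the taxa.
#' @return list with \code{dataset} (filtered phytab, input order preserved)
#'   and \code{log} (data.frame: round, type, name, reason).
#' @export
filter_coverage <- function(d, min_genes_per_species = 0,
                            min_species_per_gene = 0,
                            min_aligned_length = 0,
                            species_list = NULL) {
  stopifnot(min_genes_per_species >= 0, min_species_per_gene >= 0,
            min_aligned_length >= 0)
  partition_lengths(d)  # validates alignment uniformity
  log <- data.frame(round = integer(), type = character(), name = character(),
                    reason = character(), stringsAsFactors = FALSE)
  note <- function(round, type, name, reason) {
    rbind(log, data.frame(round = round, type = type, name = name,
                          reason = reason, stringsAsFactors = FALSE))
  }
  keep <- rep(TRUE, nrow(d))
  if (!is.null(species_list)) {
    gone <- setdiff(unique(d$species), species_list)
    for (s in gone) log <- note(0L, "species", s, "not in species list")
    keep <- keep & d$species %in% species_list
  }
  lens <- partition_lengths(d)
  short <- names(lens)[lens < min_aligned_length]
  for (p in short)
    log <- note(0L, "partition", p,
                sprintf("aligned length %d < %d", lens[[p]], min_aligned_length))
  keep <- keep & !(d$partition %in% short)

  # alternate the two occupancy rules until a full cycle changes nothing;
  # each rule application that removes something counts as one round, so a
  # species stranded by a gene removal shows up in the following round
  alive_sp <- unique(d$species[keep])
  round <- 0L; idle <- 0L; phase <- "partition"
  while (idle < 2L && any(keep)) {
    sub <- d[keep, , drop = FALSE]
    changed <- FALSE
    if (phase == "partition") {
      sp_per_gene <- tapply(sub$species, sub$partition,
                            function(x) length(unique(x)))
      weak <- names(sp_per_gene)[sp_per_gene < min_species_per_gene]
      if (length(weak)) {
        round <- round + 1L
        for (p in weak)
          log <- note(round, "partition", p,
                      sprintf("%d species < min_species_per_gene %d",
                              sp_per_gene[[p]], min_species_per_gene))
        keep <- keep & !(d$partition %in% weak)
        changed <- TRUE
      }
    } else {
      g_per_sp <- vapply(alive_sp, function(s)
        length(unique(sub$partition[sub$species == s])), integer(1))
      weak_sp <- alive_sp[g_per_sp < min_genes_per_species]
      if (length(weak_sp)) {
        round <- round + 1L
        for (s in weak_sp)
          log <- note(round, "species", s,
                      sprintf("%d partitions < min_genes_per_species %d",
                              g_per_sp[[match(s, alive_sp)]],
                              min_genes_per_species))
        alive_sp <- setdiff(alive_sp, weak_sp)
        keep <- keep & !(d$species %in% weak_sp)
        changed <- TRUE
      }
    }
    idle <- if (changed) 0L else idle + 1L
    phase <- if (phase == "partition") "species" else "partition"
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(d)
  attr(out, "provenance") <- attr(d, "provenance")
  if (nrow(out) == 0) warning("coverage filtering removed every record")
  list(dataset = out, log = log)
}

looks_like_nucleotide <- function(seqs) {
  chars <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
  chars <- chars[!chars %in% c("-", "?", "N", "X")]
  if (!length(chars)) return(TRUE)
  mean(chars %in% c("A", "C", "G", "T", "U")) >= 0.9
}

#' Read a two-column partition/model table
#'
#' Tab-delimited, gene name in the first column and best-fit model name in
#' the second -- the format produced by per-gene model-selection runs.
#'
#' @param x path or text (lines of \code{gene<TAB>model}).
#' @return named character vector, partition -> model.
#' @export
read_model_table <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]]
  else x
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) return(stats::setNames(character(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 2L))
    stop("model table lines must have 2 tab-separated columns")
  stats::setNames(vapply(f, `[`, character(1), 2),
                  vapply(f, `[`, character(1), 1))
}

#' Build a supermatrix from a filtered phytab dataset
#'
#' Concatenates partitions in order of first appearance; species rows are
#' likewise ordered by first appearance. Cells where a species lacks a
#' partition are filled with \code{missing_char} repeated to the partition's
#' aligned length. Each partition receives a model from \code{models}, or a
#' default by alphabet ("GTR" for nucleotide-looking partitions, "WAG"
#' otherwise). At most one record per (species, partition) is allowed;
#' duplicates raise an error pointing at [find_duplicates()].
#'
#' @param d a (typically coverage-filtered) phytab dataset.
#' @param models named character vector or model-table text/path
#'   (see [read_model_table()]); missing partitions take the default.
#' @param missing_char fill symbol for absent cells (default \code{"?"}).
#' @param default_model override for the alphabet-based default model.
#' @return list of class \code{"supermatrix_build"} with:
#'   \code{supermatrix} (class \code{"supermatrix"}: \code{seqs} named
#'   character vector, \code{scheme} data.frame partition/model/start/end,
#'   1-based inclusive), \code{coverage} (class \code{"coverage_matrix"}),
#'   \code{species} (ordered species list) and \code{summary} (data.frame:
#'   partition, model, length, n_species).
#' @export
build_supermatrix <- function(d, models = NULL, missing_char = "?",
                              default_model = NULL) {
  validate_phytab(d)
  if (nrow(d) == 0) stop("cannot build a supermatrix from an empty dataset")
  stopifnot(nchar(missing_char) == 1)
  lens <- partition_lengths(d)
  dupkey <- paste(d$species, d$partition, sep = "\t")
  if (anyDuplicated(dupkey))
    stop("duplicate (species, partition) record(s): ",
         gsub("\t", "/", dupkey[duplicated(dupkey)][1]),
         "; resolve with find_duplicates() first")
  if (is.character(models) && is.null(names(models)))
    models <- read_model_table(models)
  parts <- unique(d$partition)
  species <- unique(d$species)
  model_of <- vapply(parts, function(p) {
    if (!is.null(models) && p %in% names(models)) return(models[[p]])
    if (!is.null(default_model)) return(default_model)
    if (looks_like_nucleotide(d$sequence[d$partition == p])) "GTR" else "WAG"
  }, character(1))

  presence <- matrix(FALSE, nrow = length(parts), ncol = length(species),
                     dimnames = list(parts, species))
  seqs <- matrix("", nrow = length(species), ncol = length(parts),
                 dimnames = list(species, parts))
  for (p in parts) {
    rows <- d[d$partition == p, , drop = FALSE]
    presence[p, rows$species] <- TRUE
    seqs[, p] <- strrep(missing_char, lens[[p]])
    seqs[rows$species, p] <- rows$sequence
  }
  rows_cat <- apply(seqs, 1, paste, collapse = "")
  ends <- cumsum(lens)
  scheme <- data.frame(partition = parts, model = unname(model_of),
                       start = as.integer(ends - lens + 1L),
                       end = as.integer(ends),
                       stringsAsFactors = FALSE)
  sm <- structure(list(seqs = rows_cat, scheme = scheme,
                       missing_char = missing_char),
                  class = "supermatrix")
  cov <- structure(list(presence = presence,
                        lengths = lens,
                        models = stats::setNames(unname(model_of), parts)),
                  class = "coverage_matrix")
  summary <- data.frame(partition = parts, model = unname(model_of),
                        length = as.integer(unname(lens)),
                        n_species = as.integer(rowSums(presence)),
                        stringsAsFactors = FALSE)
  structure(list(supermatrix = sm, coverage = cov,
                 species = species, summary = summary),
            class = "supermatrix_build")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix: ", length(x$seqs), " species x ",
      if (length(x$seqs)) nchar(x$seqs[[1]]) else 0, " sites, ",
      nrow(x$scheme), " partition(s)\n", sep = "")
  invisible(x)
}

#' @export
print.supermatrix_build <- function(x, ...) {
  print(x$supermatrix)
  occ <- mean(x$coverage$presence)
  cat(sprintf("occupancy: %.1f%%\n", 100 * occ))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Extract one partition's columns from a supermatrix
#'
#' @param m a supermatrix.
#' @param partition partition label present in the scheme.
#' @return named character vector of the partition's aligned block, one
#'   entry per species row.
#' @export
extract_partition <- function(m, partition) {
  i <- match(partition, m$scheme$partition)
  if (is.na(i)) stop("unknown partition: ", partition)
  substr(m$seqs, m$scheme$start[i], m$scheme$end[i])
}

# ---- supermatrix I/O -------------------------------------------------------

#' Write a supermatrix (phylipE, FASTA, Nexus or strict phylip)
#'
#' \code{phylipE} is relaxed sequential phylip: a \code{"ntax nchar"}
#' header, then one \code{"name sequence"} line per species with names
#' untruncated and a single space separator. \code{phylip-strict} pads or
#' truncates names to 10 characters and refuses name collisions. Nexus
#' output is a sequential DATA block.
#'
#' @param m a \code{"supermatrix"} (or the list returned by
#'   [build_supermatrix()]).
#' @param format one of \code{"phylipE"}, \code{"fasta"}, \code{"nexus"},
#'   \code{"phylip-strict"}.
#' @param path optional output file; text returned when \code{NULL}.
#' @return the serialized text (invisibly when written to \code{path}).
#' @export
write_supermatrix <- function(m, format = c("phylipE", "fasta", "nexus",
                                            "phylip-strict"),
                              path = NULL) {
  format <- match.arg(format)
  if (inherits(m, "supermatrix_build")) m <- m$supermatrix
  seqs <- m$seqs
  ntax <- length(seqs); nchar_ <- if (ntax) nchar(seqs[[1]]) else 0
  txt <- switch(format,
    "phylipE" = paste0(ntax, " ", nchar_, "\n",
                       paste0(names(seqs), " ", seqs, "\n", collapse = "")),
    "fasta" = paste0(">", names(seqs), "\n", seqs, "\n", collapse = ""),
    "phylip-strict" = {
      nm <- substr(names(seqs), 1, 10)
      if (anyDuplicated(nm))
        stop("phylip-strict name collision after 10-character truncation: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
      paste0(ntax, " ", nchar_, "\n",
             paste0(formatC(nm, width = -10), " ", seqs, "\n", collapse = ""))
    },
    "nexus" = {
      dt <- if (looks_like_nucleotide(seqs)) "DNA" else "PROTEIN"
      paste0("#NEXUS\nBEGIN DATA;\n  DIMENSIONS NTAX=", ntax,
             " NCHAR=", nchar_, ";\n  FORMAT DATATYPE=", dt,
             " MISSING=", m$missing_char %||% "?",
             " GAP=- INTERLEAVE=NO;\n  MATRIX\n",
             paste0("    ", names(seqs), " ", seqs, "\n", collapse = ""),
             "  ;\nEND;\n")
    })
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Read an alignment file (relaxed phylip, strict phylip, FASTA or Nexus)
#'
#' Format is auto-detected: \code{>} means FASTA, \code{#NEXUS} means a
#' Nexus DATA block, otherwise relaxed phylip (\code{ntax nchar} header then
#' whitespace-separated name/sequence lines, which also covers
#' phylip-strict output).
#'
#' @param x path or text content.
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]]
  else x
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) stop("empty alignment input")
  if (startsWith(trimws(lines[1]), ">"))
    return(read_fasta(paste(lines, collapse = "\n")))
  if (grepl("^#NEXUS", toupper(trimws(lines[1]))))
    return(read_nexus_matrix(lines))
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("phylip parse error: expected 'ntax nchar' header")
  ntax <- as.integer(hdr[1]); nchar_ <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) < ntax)
    stop("phylip parse error: header declares ", ntax, " taxa, found ",
         length(body), " lines")
  f <- strsplit(trimws(body[seq_len(ntax)]), "\\s+")
  nm <- vapply(f, `[`, character(1), 1)
  sq <- vapply(f, function(v) paste(v[-1], collapse = ""), character(1))
  nm <- trimws(nm)
  if (any(nchar(sq) != nchar_))
    stop("phylip parse error: sequence length != declared nchar for taxon ",
         nm[which(nchar(sq) != nchar_)[1]])
  stats::setNames(sq, nm)
}

read_nexus_matrix <- function(lines) {
  up <- toupper(lines)
  i0 <- grep("^\\s*MATRIX\\s*$", up)
  if (!length(i0)) stop("nexus parse error: no MATRIX block")
  body <- character(); i <- i0[1] + 1L
  while (i <= length(lines) && !grepl("^\\s*;", lines[i])) {
    body <- c(body, lines[i]); i <- i + 1L
  }
  f <- strsplit(trimws(body), "\\s+")
  f <- f[lengths(f) >= 2]
  stats::setNames(vapply(f, function(v) paste(v[-1], collapse = ""), character(1)),
                  vapply(f, `[`, character(1), 1))
}

#' Write a RAxML-style partition file
#'
#' One line per partition: \code{"MODEL, name = start-end"} with 1-based
#' inclusive coordinates.
#'
#' @param scheme a partition scheme data.frame (partition, model, start,
#'   end) or an object carrying one (\code{supermatrix} /
#'   [build_supermatrix()] result).
#' @param path optional output file.
#' @return the partition-file text (invisibly when written).
#' @export
write_partitions <- function(scheme, path = NULL) {
  if (inherits(scheme, "supermatrix_build")) scheme <- scheme$supermatrix
  if (inherits(scheme, "supermatrix")) scheme <- scheme$scheme
  stopifnot(all(c("partition", "model", "start", "end") %in% names(scheme)))
  txt <- paste0(scheme$model, ", ", scheme$partition, " = ",
                scheme$start, "-", scheme$end, "\n", collapse = "")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Gene-coverage (occupancy) report
#'
#' One row per partition: gene name, assigned model, then one cell per
#' species -- 1/0 in TSV, a filled (black) or empty (white) cell in HTML --
#' showing presence or absence of that gene for each taxon.
#'
#' @param cov a \code{"coverage_matrix"} (from [build_supermatrix()]).
#' @param format \code{"tsv"} or \code{"html"}.
#' @param path optional output file.
#' @return report text (invisibly when written).
#' @export
coverage_report <- function(cov, format = c("tsv", "html"), path = NULL) {
  format <- match.arg(format)
  if (inherits(cov, "supermatrix_build")) cov <- cov$coverage
  stopifnot(inherits(cov, "coverage_matrix"))
  pres <- cov$presence
  if (format == "tsv") {
    hdr <- paste(c("partition", "model", "length", colnames(pres)),
                 collapse = "\t")
    rows <- vapply(rownames(pres), function(p) {
      paste(c(p, cov$models[[p]], cov$lengths[[p]],
              as.integer(pres[p, ])), collapse = "\t")
    }, character(1))
    txt <- paste0(paste(c(hdr, rows), collapse = "\n"), "\n")
  } else {
    cell <- function(on)
      if (on) '<td class="present" style="background:#000">&nbsp;</td>'
      else '<td class="absent" style="background:#fff">&nbsp;</td>'
    rows <- vapply(rownames(pres), function(p) {
      paste0("<tr><td>", p, "</td><td>", cov$models[[p]], "</td><td>",
             cov$lengths[[p]], "</td>",
             paste(vapply(pres[p, ], cell, character(1)), collapse = ""),
             "</tr>")
    }, character(1))
    txt <- paste0(
      "<html><body><table border=\"1\">\n<tr><th>partition</th>",
      "<th>model</th><th>length</th>",
      paste0("<th>", colnames(pres), "</th>", collapse = ""),
      "</tr>\n", paste(rows, collapse = "\n"),
      "\n</table></body></html>\n")
  }
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Concatenate per-gene alignment files into a supermatrix
#'
#' Each input file holds one aligned partition whose labels are species
#' names; the file stem becomes the partition name. Files are converted to
#' phytab records and passed through [build_supermatrix()], so the result
#' is identical to running the equivalent phytab input.
#'
#' @param files paths to FASTA / phylip / Nexus alignment files.
#' @param ... passed to [build_supermatrix()].
#' @return a [build_supermatrix()] result.
#' @export
concat_alignments <- function(files, ...) {
  if (!length(files)) stop("no alignment files given")
  recs <- lapply(files, function(f) {
    a <- read_alignment(f)
    phytab(names(a), rep(tools::file_path_sans_ext(basename(f)), length(a)),
           names(a), unname(a), provenance = f)
  })
  d <- do.call(rbind, lapply(recs, as.data.frame))
  d <- phytab(d$species, d$partition, d$uid, d$sequence,
              provenance = "concat_alignments")
  build_supermatrix(d, ...)
}
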