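# Per-partition alignment and sequence QC filters.
# An "alignment" here is a named character vector of equal-length sequences
# with unique labels; gap symbols are '-' and '?' ('?' doubles as missing
# data for morphology).

GAP_CHARS <- c("-", "?")

#' Coerce to an alignment (named character vector, equal lengths)
#'
#' @param x named character vector of sequences, or a phytab dataset holding
#'   a single partition (labels = species).
#' @return validated named character vector.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "phytab")) {
    if (length(unique(x$partition)) > 1L)
      stop("phytab input spans multiple partitions; extract one first")
    x <- stats::setNames(x$sequence, x$species)
  }
  if (!is.character(x) || is.null(names(x)) || any(names(x) == ""))
    stop("alignment must be a named character vector")
  if (anyDuplicated(names(x)))
    stop("alignment labels must be unique: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (length(unique(nchar(x))) > 1L)
    stop("alignment rows differ in length (", paste(unique(nchar(x)), collapse = ", "), ")")
  x
}

aln_matrix <- function(a) {
  m <- do.call(rbind, strsplit(unname(a), ""))
  rownames(m) <- names(a)
  m
}

matrix_aln <- function(m) {
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Mask alignment columns by gap fraction
#'
#' Removes every column whose gap fraction (proportion of \code{-} or
#' \code{?} symbols) strictly exceeds \code{max_gap_fraction}; remaining
#' columns keep their relative order. The strict inequality makes
#' \code{max_gap_fraction = 1} the identity, while \code{0} removes every
#' column containing any gap.
#'
#' @param a an alignment (see [as_alignment()]).
#' @param max_gap_fraction maximum tolerated gap proportion, in \[0, 1\].
#' @return list with \code{alignment} (masked) and \code{removed}
#'   (1-based indices of dropped columns).
#' @examples
#' mask_columns(c(s1 = "A-T", s2 = "AGT", s3 = "A-T"), 0.5)
#' @export
mask_columns <- function(a, max_gap_fraction) {
  a <- as_alignment(a)
  stopifnot(length(max_gap_fraction) == 1, max_gap_fraction >= 0,
            max_gap_fraction <= 1)
  if (!length(a) || nchar(a[1]) == 0)
    return(list(alignment = a, removed = integer()))
  m <- aln_matrix(a)
  gapfrac <- colMeans(matrix(m %in% GAP_CHARS, nrow = nrow(m)))
  drop <- which(gapfrac > max_gap_fraction)
  if (length(drop) == ncol(m)) {
    warning("all columns removed; empty alignment returned")
    return(list(alignment = stats::setNames(rep("", length(a)), names(a)),
                removed = drop))
  }
  keep <- if (length(drop)) m[, -drop, drop = FALSE] else m
  list(alignment = matrix_aln(keep), removed = drop)
}

#' Pairwise sequence identity
#'
#' Identity is matches / compared positions, where compared positions are
#' those jointly non-gap within the overlap of the two sequences (sequences
#' of unequal length are compared over the shorter length). Pairs with no
#' comparable position score 0.
#'
#' @param x,y sequences (character strings).
#' @return identity in \[0, 1\].
#' @export
pairwise_identity <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0) return(0)
  cx <- strsplit(substr(x, 1, n), "")[[1]]
  cy <- strsplit(substr(y, 1, n), "")[[1]]
  ok <- !(cx %in% GAP_CHARS) & !(cy %in% GAP_CHARS)
  if (!any(ok)) return(0)
  sum(cx[ok] == cy[ok]) / sum(ok)
}

#' Remove near-identical sequences within each partition
#'
#' Greedy first-wins representative selection: within each partition,
#' records are scanned in input order and a record is dropped when its
#' pairwise identity to any already-kept record of that partition is at or
#' above \code{identity_threshold}. Records in different partitions are
#' never compared. The procedure is deterministic and order-stable, and
#' every kept pair within a partition ends below the threshold.
#'
#' @param d a phytab dataset.
#' @param identity_threshold drop threshold in (0, 1\].
#' @return list with \code{dataset} (filtered phytab) and \code{report}
#'   (data.frame: partition, dropped uid/species, kept record it matched,
#'   identity).
#' @export
remove_similar <- function(d, identity_threshold = 0.9) {
  validate_phytab(d)
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  keep <- logical(nrow(d))
  rep_rows <- data.frame(partition = character(), dropped = character(),
                         kept = character(), identity = numeric(),
                         stringsAsFactors = FALSE)
  for (p in unique(d$partition)) {
    rows <- which(d$partition == p)
    kept <- integer()
    for (i in rows) {
      ids <- vapply(kept, function(j) pairwise_identity(d$sequence[i], d$sequence[j]),
                    numeric(1))
      hit <- which(ids >= identity_threshold)
      if (length(hit)) {
        j <- kept[hit[1]]
        rep_rows <- rbind(rep_rows, data.frame(
          partition = p,
          dropped = record_id(d, i), kept = record_id(d, j),
          identity = ids[hit[1]], stringsAsFactors = FALSE))
      } else {
        kept <- c(kept, i); keep[i] <- TRUE
      }
    }
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(d)
  attr(out, "provenance") <- attr(d, "provenance")
  list(dataset = out, report = rep_rows)
}

record_id <- function(d, i) {
  if (d$uid[i] != "") d$uid[i] else paste0(d$species[i], "@", i)
}

#' Flag sequences much shorter than their group's average
#'
#' Computes the ungapped length of every sequence and flags those strictly
#' below \code{fraction} times the mean ungapped length of their group --
#' each partition separately for phytab input, the whole file for FASTA
#' input. With the default \code{fraction = 1} this is simply
#' "shorter than average".
#'
#' @param seqs a phytab dataset, FASTA content/path, or named character
#'   vector of sequences.
#' @param fraction positive multiplier of the mean defining the cutoff.
#' @return data.frame report: partition, id, length, mean_length, cutoff
#'   (one row per flagged sequence).
#' @export
length_outliers <- function(seqs, fraction = 1.0) {
  stopifnot(fraction > 0)
  if (inherits(seqs, "phytab")) {
    validate_phytab(seqs)
    if (nrow(seqs) == 0) stop("need at least one sequence")
    part <- seqs$partition
    ids <- mapply(record_id, i = seq_len(nrow(seqs)),
                  MoreArgs = list(d = seqs))
    sq <- seqs$sequence
  } else {
    if (is.character(seqs) && (length(seqs) > 1L || grepl("[>\n]", seqs) ||
                               (is.null(names(seqs)) && file.exists(seqs))))
      seqs <- read_fasta(seqs)
    if (!length(seqs)) stop("need at least one sequence")
    part <- rep("all", length(seqs))
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    sq <- unname(seqs)
  }
  len <- nchar(gsub("[-?]", "", sq))
  out <- do.call(rbind, lapply(unique(part), function(p) {
    i <- which(part == p)
    mu <- mean(len[i]); cut <- fraction * mu
    flag <- i[len[i] < cut]
    data.frame(partition = rep(p, length(flag)), id = ids[flag],
               length = len[flag], mean_length = rep(mu, length(flag)),
               cutoff = rep(cut, length(flag)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
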