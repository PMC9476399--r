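#' Construct a PhIP-Seq peptide count matrix
#'
#' The central data container: a peptides-by-samples matrix of sequencing
#' read counts with per-sample roles distinguishing beads-only (mock
#' immunoprecipitation, no antibody input) controls from serum samples.
#' Library sizes (total read counts, the binomial denominators) are computed
#' as column sums at construction and recomputed after any peptide removal.
#'
#' @param counts Non-negative integer matrix, peptides in rows and samples
#'   in columns. Row names are taken as peptide identifiers and column names
#'   as sample identifiers unless given explicitly.
#' @param roles Character vector, one of \code{"beads"} or \code{"serum"}
#'   per sample.
#' @param peptide_ids,sample_ids Optional identifier vectors overriding the
#'   dimnames of \code{counts}. Must be unique.
#'
#' @return An object of class \code{"PeptideCountMatrix"}: a list with
#'   elements \code{counts} (named integer matrix) and \code{samples}
#'   (data frame with columns \code{sample_id}, \code{role},
#'   \code{lib_size}).
#'
#' @details At least two beads-only samples are required by the downstream
#'   prior and dispersion estimators; the constructor records roles but does
#'   not enforce this, so that degenerate objects can be built for
#'   diagnostics.
#'
#' @examples
#' y <- matrix(rpois(12, 50), nrow = 4,
#'             dimnames = list(paste0("pep_", 1:4), paste0("s", 1:3)))
#' m <- phip_counts(y, roles = c("beads", "beads", "serum"))
#' library_sizes(m)
#' @export
phip_counts <- function(counts, roles, peptide_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(peptide_ids)) peptide_ids <- paste0("pep_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  peptide_ids <- as.character(peptide_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(peptide_ids)) format_error("duplicated peptide ids")
  if (anyDuplicated(sample_ids)) format_error("duplicated sample ids")
  if (length(peptide_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    format_error("identifier lengths do not match count matrix dimensions")
  if (!is.numeric(counts) || anyNA(counts))
    format_error("counts must be numeric with no missing values")
  if (any(counts < 0)) format_error("counts must be non-negative")
  if (any(counts != round(counts))) format_error("counts must be integers")
  storage.mode(counts) <- "double" # counts can exceed .Machine$integer.max in sums
  dimnames(counts) <- list(peptide_ids, sample_ids)

  roles <- as.character(roles)
  if (length(roles) != ncol(counts))
    consistency_error("one role per sample is required")
  if (!all(roles %in% c("beads", "serum")))
    format_error("roles must be 'beads' or 'serum'")

  m <- structure(list(
    counts = counts,
    samples = data.frame(sample_id = sample_ids, role = roles,
                         lib_size = colSums(counts),
                         row.names = sample_ids)
  ), class = "PeptideCountMatrix")
  m
}

#' Read a count matrix and sample annotation from delimited text
#'
#' Expects a tab-delimited counts file whose header row holds sample ids and
#' whose first column (named \code{peptide_id}) holds peptide ids, and a
#' two-column annotation file mapping \code{sample_id} to \code{role}
#' (\code{beads} or \code{serum}).
#'
#' @param counts_path Path to the TSV count matrix.
#' @param annotation_path Path to the TSV sample annotation.
#' @return A \code{\link{phip_counts}} object with library sizes computed as
#'   column sums.
#' @export
read_counts <- function(counts_path, annotation_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) format_error("counts file needs a peptide id column and at least one sample")
  peptide_ids <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(counts)) format_error("non-numeric entries in counts file")
  annot <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(annot)))
    format_error("annotation file must have columns 'sample_id' and 'role'")
  missing <- setdiff(colnames(counts), annot$sample_id)
  if (length(missing))
    consistency_error(paste0("samples missing from annotation: ",
                             paste(missing, collapse = ", ")))
  roles <- annot$role[match(colnames(counts), annot$sample_id)]
  phip_counts(counts, roles, peptide_ids = peptide_ids,
              sample_ids = colnames(counts))
}

#' Write a count matrix and its sample annotation as TSV
#'
#' Inverse of \code{\link{read_counts}}; a write/read round trip reproduces
#' counts, roles, and library sizes exactly.
#'
#' @param m A \code{PeptideCountMatrix}.
#' @param counts_path,annotation_path Output file paths.
#' @return Invisibly, \code{m}.
#' @export
write_counts <- function(m, counts_path, annotation_path) {
  stopifnot(inherits(m, "PeptideCountMatrix"))
  tab <- data.frame(peptide_id = rownames(m$counts), m$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$samples[, c("sample_id", "role")], annotation_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @export
dim.PeptideCountMatrix <- function(x) dim(x$counts)

#' @export
print.PeptideCountMatrix <- function(x, ...) {
  cat(sprintf("PeptideCountMatrix: %d peptides x %d samples (%d beads-only, %d serum)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$role == "beads"), sum(x$samples$role == "serum")))
  cat("library sizes:", paste(format(x$samples$lib_size, big.mark = ","),
                              collapse = " "), "\n")
  invisible(x)
}

#' Sample ids by role
#'
#' @param m A \code{PeptideCountMatrix}.
#' @return Character vector of sample ids.
#' @export
beads_ids <- function(m) m$samples$sample_id[m$samples$role == "beads"]

#' @rdname beads_ids
#' @export
serum_ids <- function(m) m$samples$sample_id[m$samples$role == "serum"]

#' Library sizes (total read count per sample)
#' @param m A \code{PeptideCountMatrix}.
#' @return Named numeric vector of column totals.
#' @export
library_sizes <- function(m) stats::setNames(m$samples$lib_size, m$samples$sample_id)

#' Drop peptides and recompute library sizes
#'
#' Removes the given peptides from every sample and recomputes library sizes
#' as the column sums of the remaining counts.
#'
#' @param m A \code{PeptideCountMatrix}.
#' @param drop Character vector of peptide ids to remove.
#' @return A \code{PeptideCountMatrix} without the dropped peptides.
#' @export
drop_peptides <- function(m, drop) {
  stopifnot(inherits(m, "PeptideCountMatrix"))
  unknown <- setdiff(drop, rownames(m$counts))
  if (length(unknown))
    argument_error(paste0("unknown peptide ids: ", paste(unknown, collapse = ", ")))
  keep <- setdiff(rownames(m$counts), drop)
  phip_counts(m$counts[keep, , drop = FALSE], roles = m$samples$role)
}

#' Relabel one beads-only sample as serum for round-robin analysis
#'
#' For false-positive assessment, each mock IP is held out in turn and
#' analysed as if it were a serum sample against the remaining beads-only
#' controls. Counts are unchanged; only the role label of \code{held_out}
#' flips from \code{beads} to \code{serum}.
#'
#' @param m A \code{PeptideCountMatrix}.
#' @param held_out Sample id of a beads-only sample.
#' @return A \code{PeptideCountMatrix} with identical counts and the held-out
#'   sample relabeled \code{serum}.
#' @export
leave_one_beads_out <- function(m, held_out) {
  stopifnot(inherits(m, "PeptideCountMatrix"))
  if (!held_out %in% m$samples$sample_id)
    argument_error(paste0("unknown sample id: ", held_out))
  if (m$samples[held_out, "role"] != "beads")
    argument_error(paste0(held_out, " is not a beads-only sample"))
  roles <- ifelse(m$samples$sample_id == held_out, "serum", m$samples$role)
  phip_counts(m$counts, roles)
}
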