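# File formats: the count-table TSV dialect, transversion-site lists,
# and FASTA (via Biostrings). Coordinates are 1-based and inclusive
# throughout, matching the rCRS/Phylotree convention.

#' Write a per-site transition count table
#'
#' TSV with a header row (`site`, `transitions`) preceded by a `#`
#' comment stating the 1-based coordinate convention. One row per site,
#' covering sites 1..n completely.
#'
#' @param counts non-negative integer vector; row `i` is site `i`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(counts, path) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    pc_contract_error("counts must be non-negative integers")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-site transition counts; `site` is 1-based (rCRS-style coordinates)", con)
  utils::write.table(
    data.frame(site = seq_along(counts), transitions = as.integer(counts)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a transversion-site list
#'
#' One 1-based site index per line; `#` comments allowed.
#'
#' @param sites integer vector of 1-based site indices.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_transversion_sites <- function(sites, path) {
  sites <- as.integer(sites)
  if (anyNA(sites) || any(sites < 1L)) {
    pc_contract_error("transversion sites must be 1-based indices")
  }
  writeLines(c("# phylogeny transversion sites (1-based)",
               as.character(sort(unique(sites)))), path)
  invisible(path)
}

#' Load a phylogeny summary from a count table and a transversion list
#'
#' Parses and validates the two-file contract: a TSV of per-site
#' transition counts (columns `site`, `transitions`; sites must be the
#' complete 1-based range with no duplicates) and a list of phylogeny
#' transversion sites (one 1-based index per line, `#` comments allowed).
#'
#' @param counts_file path to the count-table TSV.
#' @param transversions_file path to the transversion-site list.
#' @return an object of class `phylogeny_summary`: list with
#'   `transition_counts`, `transversion_sites`, `n_sites`.
#' @export
load_phylogeny_summary <- function(counts_file, transversions_file) {
  for (f in c(counts_file, transversions_file)) {
    if (!file.exists(f)) pc_parse_error(sprintf("file not found: %s", f))
  }
  tab <- tryCatch(
    utils::read.delim(counts_file, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) pc_parse_error(sprintf(
      "cannot parse count table %s: %s", counts_file, conditionMessage(e))))
  if (!all(c("site", "transitions") %in% names(tab))) {
    pc_parse_error(sprintf(
      "count table %s must have columns 'site' and 'transitions'",
      counts_file))
  }
  site <- suppressWarnings(as.integer(tab$site))
  cnt <- suppressWarnings(as.numeric(tab$transitions))
  bad <- which(is.na(site) | is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad)) {
    pc_parse_error(sprintf("malformed row %d in %s", bad[1], counts_file))
  }
  if (any(site < 1L)) {
    pc_parse_error(sprintf(
      "site index %d in %s: sites are 1-based", min(site), counts_file))
  }
  if (anyDuplicated(site)) {
    pc_parse_error(sprintf(
      "duplicate site %d in %s (row %d)",
      site[anyDuplicated(site)], counts_file, anyDuplicated(site)))
  }
  n_sites <- max(site)
  if (length(site) != n_sites) {
    missing_site <- setdiff(seq_len(n_sites), site)[1]
    pc_parse_error(sprintf(
      "count table %s must cover sites 1..%d completely (site %d missing)",
      counts_file, n_sites, missing_site))
  }
  counts <- integer(n_sites)
  counts[site] <- as.integer(cnt)

  lines <- readLines(transversions_file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  tv <- suppressWarnings(as.integer(lines))
  if (anyNA(tv)) {
    pc_parse_error(sprintf(
      "malformed line %d in %s", which(is.na(tv))[1], transversions_file))
  }
  if (any(tv < 1L | tv > n_sites)) {
    pc_parse_error(sprintf(
      "transversion site %d out of range 1..%d in %s",
      tv[which(tv < 1L | tv > n_sites)[1]], n_sites, transversions_file))
  }
  phylogeny_summary(counts, sort(unique(tv)), n_sites)
}

#' Construct a phylogeny summary
#'
#' @param transition_counts non-negative integer vector, one per site.
#' @param transversion_sites 1-based indices of sites with at least one
#'   transversion along the phylogeny.
#' @param n_sites total number of sites (defaults to
#'   `length(transition_counts)`).
#' @return an object of class `phylogeny_summary`.
#' @export
phylogeny_summary <- function(transition_counts, transversion_sites = integer(),
                              n_sites = length(transition_counts)) {
  transition_counts <- as.integer(transition_counts)
  transversion_sites <- as.integer(transversion_sites)
  if (length(transition_counts) != n_sites) {
    pc_contract_error("transition_counts length must equal n_sites")
  }
  if (any(transition_counts < 0)) {
    pc_contract_error("transition counts must be non-negative")
  }
  if (any(transversion_sites < 1L | transversion_sites > n_sites)) {
    pc_contract_error("transversion_sites must lie in 1..n_sites")
  }
  structure(list(transition_counts = transition_counts,
                 transversion_sites = sort(unique(transversion_sites)),
                 n_sites = as.integer(n_sites)),
            class = "phylogeny_summary")
}

#' @export
print.phylogeny_summary <- function(x, ...) {
  cat(sprintf(
    "<phylogeny_summary> %d sites, %d transversion sites, %d transitions total\n",
    x$n_sites, length(x$transversion_sites), sum(x$transition_counts)))
  invisible(x)
}

#' Read the first sequence of a FASTA file
#'
#' Multi-record FASTA is allowed; the first record is used (use
#' [read_fasta_all()] for batch mode).
#'
#' @param path FASTA file.
#' @return a single upper-case character string.
#' @export
read_fasta_first <- function(path) {
  if (!file.exists(path)) pc_parse_error(sprintf("file not found: %s", path))
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) pc_parse_error(sprintf(
                     "cannot parse FASTA %s: %s", path, conditionMessage(e))))
  if (length(seqs) < 1L) pc_parse_error(sprintf("no records in %s", path))
  toupper(as.character(seqs[[1]]))
}

#' @rdname read_fasta_first
#' @return for `read_fasta_all`, a named character vector of all records.
#' @export
read_fasta_all <- function(path) {
  if (!file.exists(path)) pc_parse_error(sprintf("file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
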