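#' @keywords internal
"_PACKAGE"

# Internal coordinate convention
# ------------------------------
# All intervals held in memory are 0-based, half-open [begin, end), as in BED.
# The browser-style BPR dialect ("bpr_tsv") is 1-based and fully closed and is
# converted on read (begin - 1) and back on write.  Keeping one unambiguous
# internal convention and doing all conversion at the file boundary means the
# distance and flanking arithmetic never has to know where a table came from.

#' Normalize a gene or element name
#'
#' Names coming from expression studies and from genome annotations rarely
#' agree byte-for-byte: case differs, stray whitespace sneaks in, and
#' transcript identifiers often carry a trailing version suffix
#' (e.g. `NM_000546.6`).  Normalization uppercases, trims, and strips a final
#' `.<digits>` suffix, so that name matching fails only on genuinely different
#' identifiers.
#'
#' @param x Character vector of raw names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_gene_name(c(" tp53 ", "NM_000546.6"))
#' @export
normalize_gene_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  sub("\\.[0-9]+$", "", x)
}

# Read a whitespace/tab table robustly, keeping track of source line numbers
# for error messages.  Returns a list of character matrices rows plus the line
# number of the first data row.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

is_integer_like <- function(x) {
  grepl("^-?[0-9]+$", x)
}

# natural chromosome order: chr1 < chr2 < ... < chr22 < chrX < chrY < chrM
chrom_rank <- function(chrom) {
  key <- function(x) {
    suffix <- sub("^chr", "", x, ignore.case = TRUE)
    num <- suppressWarnings(as.numeric(suffix))
    special <- match(toupper(suffix), c("X", "Y", "M", "MT"))
    ifelse(!is.na(num), num, 1000 + ifelse(is.na(special), 99, special))
  }
  u <- unique(chrom)
  u_sorted <- u[order(key(u), u)]
  match(chrom, u_sorted)
}

order_by_chrom <- function(chrom, ...) {
  order(chrom_rank(chrom), ...)
}

#' Read a breakpoint-region (BPR) table
#'
#' Reads a table of evolutionary breakpoint regions: intervals of a reference
#' genome that underwent (or are orthologous to a region that underwent) a
#' large chromosomal structural change on some evolutionary branch.  Two
#' dialects are supported:
#'
#' * `"bpr_tsv"`: four tab- or whitespace-separated columns --
#'   chromosome, begin, end, evolutionary-branch label -- with coordinates in
#'   the 1-based fully-closed convention used by genome-browser table
#'   displays.  A header row is auto-detected (non-numeric second column).
#' * `"bed"`: standard BED with the branch label in the name column;
#'   coordinates are 0-based half-open and used as-is.
#'
#' Coordinates are converted to the internal 0-based half-open convention and
#' records are sorted by (chromosome, begin).
#'
#' @param path Path to the table.
#' @param dialect One of `"bpr_tsv"` (default) or `"bed"`.
#' @return A `data.frame` with columns `chrom`, `begin`, `end` (0-based
#'   half-open) and `branch`, sorted by (`chrom`, `begin`).
#' @seealso [write_bpr_table()], [select_breakpoints()]
#' @export
read_bpr_table <- function(path, dialect = c("bpr_tsv", "bed")) {
  dialect <- match.arg(dialect)
  src <- read_tsv_lines(path)
  if (length(src$lines) == 0L) {
    warning("BPR table ", path, " contains no data rows")
    return(empty_bpr_table())
  }
  fields <- strsplit(src$lines, "[\t ]+")
  # header detection: both coordinate columns non-numeric (a single bad
  # coordinate in a data row must stay an error, not become a header)
  first <- fields[[1L]]
  has_header <- length(first) >= 3L && !is_integer_like(first[2L]) &&
    !is_integer_like(first[3L])
  if (has_header) {
    fields <- fields[-1L]
    src$lineno <- src$lineno[-1L]
  }
  if (length(fields) == 0L) {
    warning("BPR table ", path, " contains no data rows")
    return(empty_bpr_table())
  }
  n <- length(fields)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    ln <- src$lineno[i]
    if (length(f) < 4L) {
      stop("malformed BPR row at line ", ln, ": expected 4 columns, got ",
           length(f), call. = FALSE)
    }
    if (!is_integer_like(f[2L]) || !is_integer_like(f[3L])) {
      stop("malformed BPR row at line ", ln, ": non-integer coordinate",
           call. = FALSE)
    }
    b <- as.numeric(f[2L]); e <- as.numeric(f[3L])
    if (b > e) {
      stop("malformed BPR row at line ", ln, ": begin > end", call. = FALSE)
    }
    if (b < 0) {
      stop("malformed BPR row at line ", ln, ": negative coordinate",
           call. = FALSE)
    }
    if (!nzchar(f[4L])) {
      stop("malformed BPR row at line ", ln, ": empty branch label",
           call. = FALSE)
    }
    rows[[i]] <- list(chrom = f[1L], begin = b, end = e, branch = f[4L])
  }
  out <- data.frame(
    chrom  = vapply(rows, `[[`, character(1), "chrom"),
    begin  = vapply(rows, `[[`, numeric(1), "begin"),
    end    = vapply(rows, `[[`, numeric(1), "end"),
    branch = vapply(rows, `[[`, character(1), "branch"),
    stringsAsFactors = FALSE
  )
  if (dialect == "bpr_tsv") {
    out$begin <- out$begin - 1  # 1-based closed -> 0-based half-open
  }
  key <- paste(out$chrom, out$begin, out$end)
  if (anyDuplicated(key)) {
    stop("duplicate BPR record(s): ", paste(unique(key[duplicated(key)]),
         collapse = "; "), call. = FALSE)
  }
  out <- out[order_by_chrom(out$chrom, out$begin, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_bpr_table <- function() {
  data.frame(chrom = character(), begin = numeric(), end = numeric(),
             branch = character(), stringsAsFactors = FALSE)
}

#' Write a BPR table
#'
#' Inverse of [read_bpr_table()]: converts the internal 0-based half-open
#' coordinates back to the dialect's convention.  A `bpr_tsv` round trip
#' reproduces the source file up to whitespace.
#'
#' @param bprs BPR `data.frame` as returned by [read_bpr_table()].
#' @param path Output path.
#' @param dialect One of `"bpr_tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_bpr_table <- function(bprs, path, dialect = c("bpr_tsv", "bed")) {
  dialect <- match.arg(dialect)
  out <- bprs[, c("chrom", "begin", "end", "branch"), drop = FALSE]
  if (dialect == "bpr_tsv") {
    out$begin <- out$begin + 1
  }
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "bpr_tsv") {
    writeLines(paste("Chromosome", "Begin", "End", "Evolutionary_branch",
                     sep = "\t"), con)
  }
  if (nrow(out) > 0L) {
    writeLines(paste(out$chrom, fmt(out$begin), fmt(out$end), out$branch,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' Reads gene intervals in one of two dialects:
#'
#' * `"bed"`: `chrom start end name [score] [strand]`, 0-based half-open.
#' * `"name_tsv"`: `name chrom start end [strand]`, 1-based fully closed
#'   (browser-style), converted on read.
#'
#' Gene names are normalized with [normalize_gene_name()].  Duplicate names
#' (multi-locus genes) are retained -- each locus is treated independently
#' downstream -- and reported in the `"duplicates"` attribute of the result.
#'
#' @param path Path to the table.
#' @param dialect One of `"bed"` (default) or `"name_tsv"`.
#' @return A `data.frame` with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"`, `"-"` or `"*"` for unknown),
#'   with a character-vector attribute `"duplicates"` listing names that occur
#'   at more than one locus.
#' @export
read_gene_table <- function(path, dialect = c("bed", "name_tsv")) {
  dialect <- match.arg(dialect)
  src <- read_tsv_lines(path)
  empty <- data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  attr(empty, "duplicates") <- character()
  if (length(src$lines) == 0L) {
    return(empty)
  }
  fields <- strsplit(src$lines, "[\t ]+")
  coord_cols <- if (dialect == "bed") c(2L, 3L) else c(3L, 4L)
  min_cols <- 4L
  first <- fields[[1L]]
  has_header <- length(first) >= min_cols &&
    !is_integer_like(first[coord_cols[1L]]) &&
    !is_integer_like(first[coord_cols[2L]])
  if (has_header) {
    fields <- fields[-1L]
    src$lineno <- src$lineno[-1L]
  }
  if (length(fields) == 0L) {
    return(empty)
  }
  n <- length(fields)
  name <- chrom <- strand <- character(n)
  start <- end <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    ln <- src$lineno[i]
    if (length(f) < min_cols) {
      stop("malformed gene row at line ", ln, ": expected at least ",
           min_cols, " columns, got ", length(f), call. = FALSE)
    }
    if (!is_integer_like(f[coord_cols[1L]]) || !is_integer_like(f[coord_cols[2L]])) {
      stop("malformed gene row at line ", ln, ": non-integer coordinate",
           call. = FALSE)
    }
    s <- as.numeric(f[coord_cols[1L]]); e <- as.numeric(f[coord_cols[2L]])
    if (s > e) {
      stop("malformed gene row at line ", ln, ": start > end", call. = FALSE)
    }
    if (dialect == "bed") {
      name[i] <- f[4L]; chrom[i] <- f[1L]
      strand[i] <- if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "*"
    } else {
      name[i] <- f[1L]; chrom[i] <- f[2L]
      s <- s - 1  # 1-based closed -> 0-based half-open
      strand[i] <- if (length(f) >= 5L && f[5L] %in% c("+", "-")) f[5L] else "*"
    }
    start[i] <- s; end[i] <- e
  }
  name <- normalize_gene_name(name)
  if (any(!nzchar(name))) {
    stop("empty gene name at line ",
         src$lineno[which(!nzchar(name))[1L]], call. = FALSE)
  }
  out <- data.frame(name = name, chrom = chrom, start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  attr(out, "duplicates") <- sort(unique(name[duplicated(name)]))
  out
}

#' Write a gene table as BED
#'
#' @param genes Gene `data.frame` as from [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(genes$chrom, fmt(genes$start), fmt(genes$end), genes$name,
                 0, genes$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression element list
#'
#' Expression studies report "genetic elements" -- gene symbols, mRNAs, ESTs
#' -- with a significant fold change between the two species.  The list is a
#' TSV with columns `raw_name` and, optionally, `direction` (`up`/`down`) and
#' `fold_change`; a header is auto-detected.  Only the DE / non-DE partition
#' is consumed by the analysis; direction and fold change are carried along
#' for reporting.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `raw_name`, `direction`
#'   (`up`/`down`/`unknown`) and `fold_change` (`NA` when absent).
#' @export
read_de_list <- function(path) {
  src <- read_tsv_lines(path)
  empty <- data.frame(raw_name = character(), direction = character(),
                      fold_change = numeric(), stringsAsFactors = FALSE)
  if (length(src$lines) == 0L) {
    warning("DE list ", path, " contains no data rows")
    return(empty)
  }
  fields <- strsplit(src$lines, "\t")
  first <- fields[[1L]]
  if (tolower(first[1L]) %in% c("raw_name", "name", "element", "gene")) {
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) {
    return(empty)
  }
  raw_name <- vapply(fields, `[[`, character(1), 1L)
  direction <- vapply(fields, function(f) {
    if (length(f) >= 2L && tolower(f[2L]) %in% c("up", "down")) tolower(f[2L])
    else "unknown"
  }, character(1))
  fold_change <- vapply(fields, function(f) {
    if (length(f) >= 3L && grepl("^-?[0-9.eE+-]+$", f[3L]))
      suppressWarnings(as.numeric(f[3L])) else NA_real_
  }, numeric(1))
  if (any(!nzchar(trimws(raw_name)))) {
    stop("empty element name in DE list", call. = FALSE)
  }
  data.frame(raw_name = raw_name, direction = direction,
             fold_change = fold_change, stringsAsFactors = FALSE)
}

#' Read a name-alias map
#'
#' Two-column TSV mapping an obsolete or study-specific name to a current
#' gene symbol.  Both sides are normalized.  Chained aliases (A -> B -> C) are
#' allowed and followed at resolution time; cycles are rejected there.
#'
#' @param path Path to the TSV (columns: old name, new name; header optional).
#' @return A named character vector: `names()` are old names, values new.
#' @export
read_alias_map <- function(path) {
  src <- read_tsv_lines(path)
  if (length(src$lines) == 0L) {
    return(stats::setNames(character(), character()))
  }
  fields <- strsplit(src$lines, "[\t ]+")
  first <- fields[[1L]]
  if (tolower(first[1L]) %in% c("old_name", "old", "alias", "from")) {
    fields <- fields[-1L]
  }
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop("malformed alias row at line ", src$lineno[bad[1L]], call. = FALSE)
  }
  old <- normalize_gene_name(vapply(fields, `[[`, character(1), 1L))
  new <- normalize_gene_name(vapply(fields, `[[`, character(1), 2L))
  stats::setNames(new, old)
}

# Follow an alias chain to its terminal name; error on a cycle.
resolve_alias <- function(name, aliases) {
  seen <- character()
  cur <- name
  while (cur %in% names(aliases)) {
    if (cur %in% seen) {
      stop("alias map cycle involving '", cur, "'", call. = FALSE)
    }
    seen <- c(seen, cur)
    cur <- unname(aliases[[cur]])
  }
  cur
}

#' Match expression elements to annotated genes
#'
#' The central name-resolution step linking an unpositioned expression study
#' to a positional gene annotation.  Each element name is normalized and
#' matched in order: exact symbol match against the annotation, then
#' alias-map lookup (chains followed) followed by exact match.  Elements that
#' resolve to no annotated gene are dropped and reported; every input element
#' lands in exactly one of `matched` / `unmatched`.
#'
#' @param elements A `data.frame` from [read_de_list()], or a character vector
#'   of raw names.
#' @param genes Gene `data.frame` from [read_gene_table()].
#' @param aliases Optional named character vector from [read_alias_map()].
#' @return A list with components:
#'   * `matched`: `data.frame` with `raw_name`, `matched_gene`, `direction`,
#'     `fold_change`;
#'   * `unmatched`: character vector of raw names with no hit;
#'   * `drop_report`: `data.frame` with `raw_name` and `reason`.
#' @export
match_expression_to_genes <- function(elements, genes, aliases = NULL) {
  if (is.character(elements)) {
    elements <- data.frame(raw_name = elements, direction = "unknown",
                           fold_change = NA_real_, stringsAsFactors = FALSE)
  }
  if (is.null(aliases)) aliases <- stats::setNames(character(), character())
  gene_names <- unique(genes$name)
  norm <- normalize_gene_name(elements$raw_name)
  matched_gene <- character(nrow(elements))
  reason <- character(nrow(elements))
  for (i in seq_along(norm)) {
    nm <- norm[i]
    if (nm %in% gene_names) {
      matched_gene[i] <- nm
    } else {
      res <- resolve_alias(nm, aliases)
      if (res != nm && res %in% gene_names) {
        matched_gene[i] <- res
      } else {
        matched_gene[i] <- NA_character_
        reason[i] <- if (res != nm) "alias target absent from annotation"
                     else "no hit in annotation"
      }
    }
  }
  hit <- !is.na(matched_gene)
  matched <- data.frame(raw_name = elements$raw_name[hit],
                        matched_gene = matched_gene[hit],
                        direction = elements$direction[hit],
                        fold_change = elements$fold_change[hit],
                        stringsAsFactors = FALSE)
  drop_report <- data.frame(raw_name = elements$raw_name[!hit],
                            reason = reason[!hit], stringsAsFactors = FALSE)
  list(matched = matched, unmatched = elements$raw_name[!hit],
       drop_report = drop_report)
}

#' Write the drop report of unmatched expression elements
#'
#' @param drop_report `data.frame` with `raw_name`, `reason`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drop_report <- function(drop_report, path) {
  utils::write.table(drop_report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
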