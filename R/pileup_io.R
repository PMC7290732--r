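#' Construct a site count table
#'
#' Container for per-site, per-sample edited-read counts `k` and total
#' coverage `n` over a two-group replicated design.  Sites are identified
#' by chromosome, 1-based position, reference base, edited base, strand
#' and (optionally empty) gene symbol; coordinates follow the mpileup
#' convention.  Strand `'.'` (unknown) is permitted; the statistics never
#' use strand.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `strand`, `gene`.
#' @param samples data.frame with columns `sample`, `group`; `group` must
#'   take exactly two values and each group needs at least one sample.
#'   Group level order (first level = reference/control) follows factor
#'   levels if `group` is a factor, else order of first appearance.
#' @param k,n Integer matrices, sites x samples, with `0 <= k <= n`.
#' @return An object of class `site_count_table`.
#' @export
site_count_table <- function(sites, samples, k, n) {
  sites <- as.data.frame(sites)
  samples <- as.data.frame(samples)
  req <- c("chrom", "pos", "ref", "alt", "strand", "gene")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("site table missing column(s): ", paste(miss, collapse = ", "))
  if (any(sites$pos < 1)) stop("positions are 1-based; found pos < 1")
  sites$ref <- toupper(sites$ref); sites$alt <- toupper(sites$alt)
  if (!all(sites$ref %in% c("A", "C", "G", "T")) ||
      !all(sites$alt %in% c("A", "C", "G", "T"))) {
    stop("ref/alt bases must be A, C, G or T")
  }
  if (any(sites$ref == sites$alt)) stop("ref and edited base must differ")
  if (!all(sites$strand %in% c("+", "-", "."))) stop("strand must be '+', '-' or '.'")
  if (!all(c("sample", "group") %in% names(samples))) {
    stop("samples needs columns 'sample' and 'group'")
  }
  if (!is.factor(samples$group)) {
    samples$group <- factor(samples$group, levels = unique(samples$group))
  }
  if (nlevels(samples$group) != 2L) {
    stop("exactly two groups are required (got ",
         nlevels(samples$group), ": ",
         paste(levels(samples$group), collapse = ", "), ")")
  }
  if (any(table(samples$group) < 1L)) stop("each group needs at least one sample")
  k <- as.matrix(k); n <- as.matrix(n)
  storage.mode(k) <- "integer"; storage.mode(n) <- "integer"
  if (!identical(dim(k), dim(n))) stop("k and n must have identical dimensions")
  if (nrow(k) != nrow(sites) || ncol(k) != nrow(samples)) {
    stop("count matrices must be sites x samples")
  }
  if (any(k < 0) || any(n < 0)) stop("counts must be non-negative")
  bad <- which(k > n, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("k > n at site %s:%d, sample %s (k=%d, n=%d)",
                 sites$chrom[bad[1, 1]], sites$pos[bad[1, 1]],
                 samples$sample[bad[1, 2]],
                 k[bad[1, 1], bad[1, 2]], n[bad[1, 1], bad[1, 2]]))
  }
  colnames(k) <- colnames(n) <- samples$sample
  rownames(k) <- rownames(n) <- site_key(sites)
  structure(list(sites = sites, samples = samples, k = k, n = n),
            class = "site_count_table")
}

site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' @export
print.site_count_table <- function(x, ...) {
  cat(sprintf("site_count_table: %d sites x %d samples (groups: %s)\n",
              nrow(x$sites), nrow(x$samples),
              paste(sprintf("%s=%d", levels(x$samples$group),
                            tabulate(x$samples$group)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.site_count_table <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a site count table by site index
#' @param x A `site_count_table`.
#' @param i Site (row) index.
#' @param ... Ignored.
#' @export
`[.site_count_table` <- function(x, i, ...) {
  site_count_table(x$sites[i, , drop = FALSE], x$samples,
                   x$k[i, , drop = FALSE], x$n[i, , drop = FALSE])
}

#' Read a site-count TSV
#'
#' Expects a tab-delimited file with header columns `chrom`, `pos`, `ref`,
#' `alt`, `strand`, `gene`, followed by paired per-sample columns
#' `<sample>_edited` and `<sample>_total`.  Lines starting with `#` are
#' ignored.  Row order is preserved.
#'
#' @param path Path to the TSV.
#' @param design Sample-to-group assignment: either a named character
#'   vector (`names` = sample ids) or a data.frame with columns `sample`
#'   and `group`.  Every design sample must be present in the file; file
#'   samples absent from the design are dropped with a message.
#' @return A [site_count_table()].
#' @export
read_site_counts <- function(path, design) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "strand", "gene")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("site-count file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.data.frame(design)) {
    smp <- design
  } else {
    smp <- data.frame(sample = names(design), group = unname(design),
                      stringsAsFactors = FALSE)
  }
  kc <- paste0(smp$sample, "_edited")
  nc <- paste0(smp$sample, "_total")
  absent <- smp$sample[!(kc %in% names(df) & nc %in% names(df))]
  if (length(absent)) {
    stop("design sample(s) not present in file: ", paste(absent, collapse = ", "))
  }
  extra <- setdiff(grep("_(edited|total)$", names(df), value = TRUE), c(kc, nc))
  if (length(extra)) message("ignoring file columns not in design: ",
                             paste(extra, collapse = ", "))
  sites <- df[req]
  sites$gene[is.na(sites$gene)] <- ""
  k <- as.matrix(df[kc]); n <- as.matrix(df[nc])
  site_count_table(sites, smp, k, n)
}

#' Write a site-count TSV
#'
#' Inverse of [read_site_counts()]; round-trips modulo float formatting.
#'
#' @param x A `site_count_table`.
#' @param path Output path.
#' @export
write_site_counts <- function(x, path) {
  stopifnot(inherits(x, "site_count_table"))
  k <- x$k; n <- x$n
  colnames(k) <- paste0(x$samples$sample, "_edited")
  colnames(n) <- paste0(x$samples$sample, "_total")
  # interleave edited/total per sample
  ord <- as.vector(rbind(seq_len(ncol(k)), ncol(k) + seq_len(ncol(n))))
  out <- cbind(x$sites, cbind(k, n)[, ord, drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse one samtools-mpileup base string into (k, n)
#'
#' Implements the mpileup text dialect: `^` + mapping-quality character
#' pairs and `$` markers are stripped; `+`/`-` indel runs (length digits
#' followed by that many bases) are skipped; `*` deletion placeholders and
#' `<`/`>` reference skips count toward neither `k` nor `n`; `.` and `,`
#' are reference calls (count to `n` only); base letters count to `n`, and
#' to `k` when they match `edited_base` case-insensitively (uppercase =
#' forward strand, lowercase = reverse).
#'
#' @param line One mpileup line (chrom, pos, ref, depth, bases, quals,
#'   tab-separated) or just the base string plus `ref`/`depth` arguments.
#' @param edited_base The substituted nucleotide to count (A/C/G/T).
#' @return Named integer vector `c(k = , n = )`.
#' @export
#' @examples
#' parse_mpileup_line("chr1\t100\tA\t6\t.GgG.,\tIIIIII", "G")
parse_mpileup_line <- function(line, edited_base) {
  edited_base <- toupper(edited_base)
  stopifnot(edited_base %in% c("A", "C", "G", "T"))
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 5L) stop("mpileup line needs >= 5 tab-separated fields")
  depth <- suppressWarnings(as.integer(fields[4]))
  bases <- strsplit(fields[5], "")[[1]]
  k <- 0L; n <- 0L; ndel <- 0L
  i <- 1L; len <- length(bases)
  while (i <= len) {
    ch <- bases[i]
    if (ch == "^") {
      i <- i + 2L                      # caret + mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= len && grepl("[0-9]", bases[j])) j <- j + 1L
      if (j == i + 1L) stop("malformed indel length at offset ", i)
      run <- as.integer(paste(bases[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + run
      if (i > len + 1L) stop("indel run exceeds base string at offset ", j)
    } else if (ch == "." || ch == ",") {
      n <- n + 1L; i <- i + 1L
    } else if (ch == "*" || ch == "<" || ch == ">") {
      ndel <- ndel + 1L; i <- i + 1L   # placeholder: neither k nor n
    } else if (toupper(ch) %in% c("A", "C", "G", "T", "N")) {
      n <- n + 1L
      if (toupper(ch) == edited_base) k <- k + 1L
      i <- i + 1L
    } else {
      stop("unrecognized pileup character '", ch, "' at offset ", i)
    }
  }
  if (!is.na(depth) && abs(depth - n) > ndel) {
    warning(sprintf("mpileup depth field (%d) disagrees with parsed n (%d); parsed value wins",
                    depth, n))
  }
  c(k = k, n = n)
}

#' Read a gene panel (one symbol per line)
#'
#' Blank lines and `#` comments are skipped.  Symbols duplicated after
#' case-normalization are deduplicated with a warning; symbols are stored
#' verbatim (first occurrence wins) and matched case-insensitively by
#' consumers.
#'
#' @param path Path to the panel file.
#' @param name Panel label; defaults to the file name without extension.
#' @return An object of class `gene_panel` with elements `name`, `genes`.
#' @export
read_gene_panel <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  genes <- trimws(readLines(path, warn = FALSE))
  genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
  if (!length(genes)) stop("gene panel '", name, "' is empty")
  dup <- duplicated(toupper(genes))
  if (any(dup)) {
    warning("panel '", name, "': ", sum(dup),
            " duplicate symbol(s) removed: ",
            paste(unique(genes[dup]), collapse = ", "))
    genes <- genes[!dup]
  }
  gene_panel(name, genes)
}

#' @rdname read_gene_panel
#' @param genes Character vector of gene symbols.
#' @export
gene_panel <- function(name, genes) {
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene panel '", name, "' is empty")
  genes <- genes[!duplicated(toupper(genes))]
  structure(list(name = name, genes = genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Construct / read an expression matrix with sample metadata
#'
#' @param values Non-negative numeric matrix, genes x samples.
#' @param meta data.frame with columns `sample`, `group`, `sex` ("M"/"F").
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, meta) {
  values <- as.matrix(values)
  meta <- as.data.frame(meta)
  if (!all(c("sample", "group", "sex") %in% names(meta))) {
    stop("sample metadata needs columns sample, group, sex")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols in expression matrix")
  if (ncol(values) != nrow(meta)) stop("metadata rows must match sample columns")
  if (!all(meta$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (!is.factor(meta$group)) meta$group <- factor(meta$group, levels = unique(meta$group))
  colnames(values) <- meta$sample
  structure(list(values = values, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (groups: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(levels(x$meta$group), collapse = "/")))
  invisible(x)
}

#' @rdname expression_matrix
#' @param path TSV with a `gene` column then one column per sample.
#' @param meta_path TSV with columns `sample`, `group`, `sex`.
#' @export
read_expression <- function(path, meta_path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("expression file needs a 'gene' column")
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  vals <- as.matrix(df[setdiff(names(df), "gene")])
  rownames(vals) <- df$gene
  absent <- setdiff(meta$sample, colnames(vals))
  if (length(absent)) stop("metadata sample(s) missing from expression file: ",
                           paste(absent, collapse = ", "))
  expression_matrix(vals[, meta$sample, drop = FALSE], meta)
}

#' Read a SILAC peptide-ratio table
#'
#' TSV with columns `protein`, `peptide`, `ratio` (heavy/light, > 0) and
#' `experiment`.
#'
#' @param path Path to the TSV.
#' @return A data.frame of class `peptide_ratio_table`.
#' @export
read_peptide_ratios <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  peptide_ratio_table(df)
}

#' @rdname read_peptide_ratios
#' @param df data.frame with the four required columns.
#' @export
peptide_ratio_table <- function(df) {
  req <- c("protein", "peptide", "ratio", "experiment")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("peptide table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$ratio)) || any(df$ratio <= 0)) {
    bad <- which(!is.finite(df$ratio) | df$ratio <= 0)[1]
    stop(sprintf("H/L ratios must be positive (row %d: protein %s, ratio %s)",
                 bad, df$protein[bad], format(df$ratio[bad])))
  }
  class(df) <- c("peptide_ratio_table", "data.frame")
  df
}
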