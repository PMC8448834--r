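#' Construct a gene set
#'
#' A gene set is a named, ordered collection of unique gene identifiers.
#' Identifiers are whitespace-trimmed and matched case-sensitively
#' throughout the package; no alias or ortholog mapping is performed.
#' Duplicate identifiers are removed (first occurrence kept) with a warning,
#' so real-world signature files with repeated rows load cleanly.
#'
#' @param name Set label.
#' @param genes Character vector of gene identifiers.
#' @param description Free-text description.
#' @return An object of class `gene_set` with elements `name`, `genes`,
#'   `description`.
#' @examples
#' gene_set("S1", c("A", "B", "C"))
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    pls_error("gene set name must be a non-empty string")
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    pls_error(sprintf("gene set '%s' is empty", name), "plsassay_parse_error")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("gene set '%s': %d duplicate gene(s) removed (%s)",
                    name, length(dup), paste(utils::head(dup, 5), collapse = ", ")),
            call. = FALSE)
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, genes = genes, description = description),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  cat(" ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# accept either a gene_set or a bare character vector
as_gene_vector <- function(s) {
  if (inherits(s, "gene_set")) s$genes else trimws(as.character(s))
}

#' Read gene sets from GMT or two-column TSV
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; lines with
#' fewer than three fields are a parse error reported with their line
#' number. The TSV dialect has two columns (set name, gene); an optional
#' header row is detected when the first cell is a common header word
#' (`set`, `set_name`, `name`, `gene_set`, `signature`, `pathway`).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"gmt"`, or `"tsv"`.
#' @return A named list of [gene_set] objects, in file order.
#' @export
load_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    pls_error(sprintf("gene set file not found: %s", path), "plsassay_input_error")
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L)
        pls_error(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i),
                  "plsassay_parse_error")
      sets[[i]] <- gene_set(f[[1]], f[-(1:2)], description = f[[2]])
    }
  } else {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             colClasses = "character", blank.lines.skip = TRUE)
    if (ncol(tab) < 2L)
      pls_error("two-column TSV gene set file expected (set name, gene)",
                "plsassay_parse_error")
    header_words <- c("set", "set_name", "name", "gene_set", "signature", "pathway")
    if (tolower(trimws(tab[1, 1])) %in% header_words) tab <- tab[-1, , drop = FALSE]
    if (nrow(tab) == 0L) pls_error("empty gene set file", "plsassay_parse_error")
    nm <- trimws(tab[[1]])
    sets <- lapply(unique(nm), function(s) gene_set(s, tab[[2]][nm == s]))
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na", s$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Build a prognostic signature
#'
#' A prognostic signature partitions its genes into a poor-prognosis set
#' (induced in high-risk tissue), a good-prognosis set (suppressed), and a
#' small housekeeping set (six genes in the reference assay) used only for
#' normalization. The three sets must be pairwise disjoint. For the named
#' versions the prognosis sets must total the declared size (186 for
#' `full-186`, 32 for `reduced-32`).
#'
#' @param poor,good,housekeeping [gene_set] objects or character vectors.
#' @param version One of `"full-186"`, `"reduced-32"`, `"custom"`, or `NULL`
#'   to infer from the total prognosis-set size.
#' @return An object of class `prognostic_signature`.
#' @export
build_signature <- function(poor, good, housekeeping, version = NULL) {
  mk <- function(x, nm) if (inherits(x, "gene_set")) x else gene_set(nm, x)
  poor <- mk(poor, "poor"); good <- mk(good, "good")
  housekeeping <- mk(housekeeping, "housekeeping")
  pairs <- list(c("poor", "good"), c("poor", "housekeeping"), c("good", "housekeeping"))
  sets <- list(poor = poor, good = good, housekeeping = housekeeping)
  for (p in pairs) {
    ov <- intersect(sets[[p[1]]]$genes, sets[[p[2]]]$genes)
    if (length(ov))
      pls_error(sprintf("gene(s) shared between %s and %s sets: %s",
                        p[1], p[2], paste(ov, collapse = ", ")),
                "plsassay_signature_error")
  }
  n_prog <- length(poor$genes) + length(good$genes)
  if (is.null(version))
    version <- if (n_prog == 186L) "full-186" else if (n_prog == 32L) "reduced-32" else "custom"
  version <- match.arg(version, c("full-186", "reduced-32", "custom"))
  declared <- c(`full-186` = 186L, `reduced-32` = 32L)
  if (version %in% names(declared) && n_prog != declared[[version]])
    pls_error(sprintf("version '%s' declares %d prognosis genes but %d were given",
                      version, declared[[version]], n_prog), "plsassay_signature_error")
  structure(list(poor = poor, good = good, housekeeping = housekeeping,
                 version = version),
            class = "prognostic_signature")
}

#' @export
print.prognostic_signature <- function(x, ...) {
  cat(sprintf("<prognostic_signature> version %s\n", x$version))
  cat(sprintf("  poor-prognosis: %d genes | good-prognosis: %d genes | housekeeping: %d genes\n",
              length(x$poor$genes), length(x$good$genes), length(x$housekeeping$genes)))
  invisible(x)
}

#' Subset a prognostic signature to a kept gene list
#'
#' Poor/good membership is preserved and the housekeeping set is unchanged.
#' The version label becomes `reduced-32` when exactly 32 genes are kept,
#' otherwise `custom`.
#'
#' @param sig A [build_signature] result.
#' @param keep Character vector of genes, all present in the signature's
#'   prognosis sets.
#' @return A new `prognostic_signature`.
#' @export
subset_signature <- function(sig, keep) {
  stopifnot(inherits(sig, "prognostic_signature"))
  keep <- trimws(as.character(keep))
  universe <- c(sig$poor$genes, sig$good$genes)
  unknown <- setdiff(keep, universe)
  if (length(unknown))
    pls_error(sprintf("kept gene(s) absent from signature: %s",
                      paste(unknown, collapse = ", ")), "plsassay_signature_error")
  poor <- sig$poor$genes[sig$poor$genes %in% keep]
  good <- sig$good$genes[sig$good$genes %in% keep]
  version <- if (length(keep) == 32L) "reduced-32" else "custom"
  build_signature(gene_set(sig$poor$name, poor),
                  gene_set(sig$good$name, good),
                  sig$housekeeping, version = version)
}

#' Report signature coverage in an expression matrix
#'
#' For each of the poor, good, and housekeeping sets, lists the genes found
#' and missing among the matrix rows and the coverage fraction
#' `found / set size`.
#'
#' @param sig A `prognostic_signature`.
#' @param m An [expr_matrix].
#' @return A list of class `signature_coverage`, one element per set with
#'   `found`, `missing`, and `coverage`.
#' @export
match_matrix <- function(sig, m) {
  stopifnot(inherits(sig, "prognostic_signature"))
  rows <- gene_ids(m)
  rep1 <- function(s) {
    found <- s$genes[s$genes %in% rows]
    list(found = found, missing = setdiff(s$genes, found),
         coverage = length(found) / length(s$genes))
  }
  structure(list(poor = rep1(sig$poor), good = rep1(sig$good),
                 housekeeping = rep1(sig$housekeeping)),
            class = "signature_coverage")
}

#' @export
print.signature_coverage <- function(x, ...) {
  cat("<signature_coverage>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %3d/%3d found (coverage %.2f)\n", nm,
                length(x[[nm]]$found),
                length(x[[nm]]$found) + length(x[[nm]]$missing),
                x[[nm]]$coverage))
  invisible(x)
}
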