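# Genotype-table text format: tab-separated with a header row, a
# "genotype" column of L-character 0/1 strings (character p is site p, in
# site_labels order), and either a "fitness" column or replicate columns
# "rep1", "rep2", ....  An optional comment line "# site_labels: a,b,..."
# precedes the header.  Rows are written in ascending integer-code order.

#' Read a genotype table
#'
#' Validates completeness (every one of the 2^L genotypes exactly once)
#' and returns a single landscape (column `fitness`) or a replicate set
#' (columns `rep1`, `rep2`, ...).
#'
#' @param path Path to a genotype-table TSV.
#' @return A `fitness_landscape`, or a `landscape_replicates` list.
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path, n = 5)
  site_labels <- NULL
  m <- grep("^#\\s*site_labels:", lines, value = TRUE)
  if (length(m) > 0) {
    site_labels <- trimws(strsplit(sub("^#\\s*site_labels:\\s*", "", m[1]), ",")[[1]])
  }
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          check.names = FALSE)
  if (!"genotype" %in% names(df)) {
    stop("parse error: missing 'genotype' column in ", path)
  }
  geno <- df$genotype
  L <- nchar(geno[1])
  bad <- which(nchar(geno) != L | grepl("[^01]", geno))
  if (length(bad) > 0) {
    stop("parse error at data line ", bad[1], ": genotype '", geno[bad[1]],
         "' is not a ", L, "-character 0/1 string")
  }
  codes <- as.integer(vapply(strsplit(geno, ""), function(b) {
    sum(as.integer(b) * 2^(seq_along(b) - 1))
  }, 0))
  if (anyDuplicated(codes)) {
    dup <- geno[duplicated(codes)][1]
    stop("parse error: duplicate genotype '", dup, "'")
  }
  missing <- setdiff(0:(2^L - 1), codes)
  if (length(missing) > 0) {
    bits <- genotype_bits(missing[1], L)[1, ]
    stop("incomplete landscape: missing genotype '",
         paste(bits, collapse = ""), "' (and ", length(missing) - 1, " more)")
  }
  value_cols <- setdiff(names(df), "genotype")
  if (length(value_cols) == 0) stop("parse error: no fitness column")
  ord <- order(codes)
  make_ls <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("parse error: non-numeric value in column '", col, "' at data line ",
           which(is.na(v))[1])
    }
    fitness_landscape(v[ord], site_labels = site_labels)
  }
  if ("fitness" %in% value_cols) return(make_ls("fitness"))
  reps <- grep("^rep[0-9]+$", value_cols, value = TRUE)
  if (length(reps) == 0) {
    stop("parse error: expected a 'fitness' or 'rep1','rep2',... column")
  }
  structure(lapply(reps, make_ls), class = "landscape_replicates",
            names = reps)
}

#' Write a genotype table
#'
#' @param x A `fitness_landscape` or `landscape_replicates`.
#' @param path Output path.
#' @param digits Significant digits to print (default: full precision via
#'   `format(..., digits = 17)`).
#' @export
write_genotype_table <- function(x, path, digits = 17) {
  reps <- .as_replicate_list(x)
  L <- reps[[1]]$L
  bits <- genotype_bits(0:(2^L - 1), L)
  geno <- apply(bits, 1, paste, collapse = "")
  df <- data.frame(genotype = geno)
  if (length(reps) == 1) {
    df$fitness <- format(reps[[1]]$fitness, digits = digits, trim = TRUE)
  } else {
    for (k in seq_along(reps)) {
      df[[paste0("rep", k)]] <- format(reps[[k]]$fitness, digits = digits,
                                       trim = TRUE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# site_labels: ",
                    paste(reps[[1]]$site_labels, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
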