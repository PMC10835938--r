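#' Default CYP2D6 star-allele function table
#'
#' Activity values per allele copy for the CYP2D6 star alleles covered by the
#' package: 0 for no-function alleles, 0.25 or 0.5 for decreased function, and
#' 1 for normal function, following current CPIC assignments. The gene
#' deletion `*5` carries value 0. The table is a plain data frame and can be
#' edited or replaced wherever an `allele_table` argument is accepted; alleles
#' absent from the table in use are always rejected, never silently scored.
#'
#' @return A data frame with columns `allele` (star-allele label, including
#'   the leading `*`) and `value` (activity value per copy).
#' @examples
#' default_allele_table()
#' @export
default_allele_table <- function() {
  data.frame(
    allele = c("*1", "*2", "*39",
               "*9", "*17", "*29", "*41", "*59", "*65", "*69", "*88",
               "*10",
               "*3", "*4", "*5", "*6", "*11", "*13"),
    value = c(1, 1, 1,
              0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
              0.25,
              0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

check_allele_table <- function(table) {
  if (!is.data.frame(table) || !all(c("allele", "value") %in% names(table)))
    stop("allele table must be a data frame with columns 'allele' and 'value'")
  if (anyDuplicated(table$allele))
    stop("allele table contains duplicated allele names: ",
         paste(unique(table$allele[duplicated(table$allele)]), collapse = ", "))
  bad <- !is.na(table$value) & !(table$value %in% c(0, 0.25, 0.5, 1))
  if (any(bad))
    stop("allele activity values must be one of 0, 0.25, 0.5, 1; offending: ",
         paste(table$allele[bad], collapse = ", "))
  if ("*5" %in% table$allele && isTRUE(table$value[table$allele == "*5"] != 0))
    stop("'*5' is the CYP2D6 gene deletion and must carry activity value 0")
  invisible(table)
}

#' Parse a CYP2D6 diplotype string
#'
#' Diplotypes are written `*A/*B`, each haplotype optionally carrying a
#' duplication suffix `xN` (e.g. `"*1x2/*5"` for a duplicated `*1` on one
#' chromosome and the gene deletion on the other). Parsing is purely
#' syntactic; whether an allele is known is checked against the function
#' table at scoring time.
#'
#' @param text A single diplotype string of the form `*<name>[xN]/*<name>[xN]`.
#' @return An object of class `cyp_diplotype`: a list with components `hap1`
#'   and `hap2` (each a list with `allele` and `copy_number`) and `raw` (the
#'   input string). Haplotype order carries no meaning; scoring is symmetric.
#' @examples
#' parse_diplotype("*4/*4")
#' parse_diplotype("*1x2/*5")
#' @export
parse_diplotype <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("diplotype must be a single character string")
  parts <- strsplit(text, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("malformed diplotype '", text, "': expected exactly one '/'")
  hap <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\*([A-Za-z0-9]+?)(?:x([0-9]+))?$", p))[[1L]]
    if (length(m) == 0L)
      stop("malformed haplotype token '", p, "' in diplotype '", text,
           "': expected *<name> with optional xN duplication suffix")
    cn <- if (m[3L] == "") 1L else as.integer(m[3L])
    if (cn < 1L)
      stop("copy number in '", p, "' must be a positive integer")
    list(allele = paste0("*", m[2L]), copy_number = cn)
  })
  structure(list(hap1 = hap[[1L]], hap2 = hap[[2L]], raw = text),
            class = "cyp_diplotype")
}

#' @export
print.cyp_diplotype <- function(x, ...) {
  cat("CYP2D6 diplotype:", x$raw, "\n")
  for (h in list(x$hap1, x$hap2))
    cat("  ", h$allele, " x", h$copy_number, "\n", sep = "")
  invisible(x)
}

#' CYP2D6 activity score of a diplotype
#'
#' The activity score (AS) is the sum over both haplotypes of the allele's
#' activity value multiplied by its copy number. Alleles missing from the
#' function table raise an error naming the allele; an allele whose value is
#' `NA` in the table yields an `NA` score (phenotype indeterminate).
#'
#' @param d A `cyp_diplotype` (from [parse_diplotype()]) or a diplotype string.
#' @param allele_table Allele function table; see [default_allele_table()].
#' @return A single numeric activity score (>= 0), or `NA` if any allele has
#'   an `NA` activity value.
#' @examples
#' activity_score("*4/*4")    # 0
#' activity_score("*1/*41")   # 1.5
#' activity_score("*1x2/*1")  # 3
#' @export
activity_score <- function(d, allele_table = default_allele_table()) {
  if (is.character(d)) d <- parse_diplotype(d)
  stopifnot(inherits(d, "cyp_diplotype"))
  check_allele_table(allele_table)
  vals <- vapply(list(d$hap1, d$hap2), function(h) {
    i <- match(h$allele, allele_table$allele)
    if (is.na(i))
      stop("allele '", h$allele, "' not present in the allele function table")
    allele_table$value[i] * h$copy_number
  }, numeric(1L))
  sum(vals)
}

#' Classify an activity score into a genotype-predicted phenotype
#'
#' Bins: AS 0 is a genetically poor metabolizer (gPM), 0 < AS < 1.25
#' intermediate (gIM), 1.25 <= AS <= 2.25 normal (gNM), AS > 2.25 ultrarapid
#' (gUM). `NA` scores classify as `"indeterminate"` (subjects whose phenotype
#' cannot be inferred from the genotype).
#'
#' @param as_value Numeric vector of activity scores (>= 0, or `NA`).
#' @return Character vector with values among `"gPM"`, `"gIM"`, `"gNM"`,
#'   `"gUM"`, `"indeterminate"`.
#' @seealso [phenotype_code()] for the ordinal numeric coding.
#' @examples
#' classify_phenotype(c(0, 1, 1.25, 2.25, 2.5))
#' @export
classify_phenotype <- function(as_value) {
  if (any(!is.na(as_value) & as_value < 0))
    stop("activity score must be non-negative")
  out <- rep(NA_character_, length(as_value))
  out[is.na(as_value)] <- "indeterminate"
  ok <- !is.na(as_value)
  x <- as_value[ok]
  out[ok] <- ifelse(x == 0, "gPM",
             ifelse(x < 1.25, "gIM",
             ifelse(x <= 2.25, "gNM", "gUM")))
  out
}

#' Ordinal numeric coding of phenotype classes
#'
#' gPM = 0, gIM = 1, gNM = 2, gUM = 3 (increasing enzyme activity);
#' `"indeterminate"` has no code and maps to `NA`. This is the target coding
#' used when tree ensembles are fitted as regressors against phenotype.
#'
#' @param phenotype Character vector of phenotype labels.
#' @return Integer vector of codes.
#' @export
phenotype_code <- function(phenotype) {
  codes <- c(gPM = 0L, gIM = 1L, gNM = 2L, gUM = 3L)
  unknown <- setdiff(unique(phenotype), c(names(codes), "indeterminate", NA))
  if (length(unknown))
    stop("unknown phenotype label(s): ", paste(unknown, collapse = ", "))
  unname(codes[phenotype])
}

#' NFIB rs28379954 sensitivity reclassification
#'
#' The NFIB rs28379954 T>C variant has been proposed to raise CYP2D6 activity
#' in genotypic normal metabolizers. When `enabled`, gNM carriers are moved to
#' gUM; every other combination is returned unchanged. This implements the
#' sensitivity re-analysis, not a claim that the reclassification holds.
#'
#' @param phenotype Character vector of phenotype labels.
#' @param carrier Logical vector, `TRUE` for rs28379954 carriers.
#' @param enabled Apply the reclassification? Default `TRUE`.
#' @return Character vector of (possibly reclassified) phenotype labels.
#' @examples
#' apply_nfib_reclassification(c("gNM", "gPM"), c(TRUE, TRUE))
#' @export
apply_nfib_reclassification <- function(phenotype, carrier, enabled = TRUE) {
  stopifnot(length(phenotype) == length(carrier))
  if (!enabled) return(phenotype)
  ifelse(phenotype == "gNM" & carrier %in% TRUE, "gUM", phenotype)
}

#' Translate a table of diplotype strings to phenotypes
#'
#' Convenience wrapper: parses each diplotype, scores it, classifies it, and
#' optionally applies the NFIB reclassification using an `nfib_carrier`
#' column.
#'
#' @param subjects Data frame with a `diplotype` column and optionally an
#'   `nfib_carrier` logical column.
#' @param allele_table Allele function table.
#' @param nfib_reclass Apply the NFIB gNM-to-gUM reclassification (requires
#'   the `nfib_carrier` column)? Default `FALSE`.
#' @return `subjects` with `activity_score` and `phenotype` columns appended.
#' @export
phenotype_subjects <- function(subjects, allele_table = default_allele_table(),
                               nfib_reclass = FALSE) {
  stopifnot(is.data.frame(subjects), "diplotype" %in% names(subjects))
  subjects$activity_score <- vapply(
    subjects$diplotype, activity_score, numeric(1L),
    allele_table = allele_table, USE.NAMES = FALSE)
  subjects$phenotype <- classify_phenotype(subjects$activity_score)
  if (nfib_reclass) {
    if (!"nfib_carrier" %in% names(subjects))
      stop("nfib_reclass = TRUE requires an 'nfib_carrier' column")
    subjects$phenotype <- apply_nfib_reclassification(
      subjects$phenotype, subjects$nfib_carrier, enabled = TRUE)
  }
  subjects
}
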