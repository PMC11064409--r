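# Vocabulary layer: configurable code sets, keyword rules and the specialist
# taxonomy that ground the code-based criteria. Code-set contents are
# deployment configuration; the defaults shipped under
# inst/extdata/synthetic_codesets/ are synthetic illustrative stand-ins, not
# clinically curated lists, and real deployments should supply their own.

#' Construct a code set
#'
#' A named collection of diagnosis/procedure codes matched either exactly or
#' by prefix. Prefix matching is the default so that a configured ICD stem
#' (e.g. "E71.0") also matches its child codes ("E71.09"), which is robust to
#' differences in coding depth between ICD-9 and ICD-10 extracts.
#'
#' @param codes character vector of codes; duplicates and blanks are dropped.
#' @param name label used in messages.
#' @param match_mode "prefix" or "exact".
#' @return An object of class `codeset`.
#' @export
#' @examples
#' cs <- codeset(c("E71.0", "E71.1", "E71.1"), "metabolic")
#' code_matches(c("E71.09", "Z38.00"), cs)
codeset <- function(codes, name = "codeset",
                    match_mode = c("prefix", "exact")) {
  match_mode <- match.arg(match_mode)
  codes <- unique(toupper(trimws(as.character(codes))))
  codes <- codes[!is.na(codes) & nzchar(codes)]
  if (!length(codes)) {
    stop("code set '", name, "' is empty", call. = FALSE)
  }
  structure(list(name = name, codes = codes, match_mode = match_mode),
            class = "codeset")
}

#' Load a code set from a delimited file
#'
#' Expects a header row and a `code` column; a `description` column is
#' optional and ignored for matching. Duplicate codes are collapsed.
#'
#' @param path file path (plain or gzipped CSV).
#' @param match_mode "prefix" or "exact".
#' @param name label; defaults to the file name.
#' @return A [codeset()].
#' @export
load_codeset <- function(path, match_mode = c("prefix", "exact"),
                         name = NULL) {
  match_mode <- match.arg(match_mode)
  if (!file.exists(path)) {
    stop("code set file not found: ", path, call. = FALSE)
  }
  name <- name %||% sub("\\.csv(\\.gz)?$", "", basename(path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("code set '", name, "' is unreadable: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) {
    stop("code set file '", path, "' has no codes", call. = FALSE)
  }
  if (!"code" %in% names(df)) {
    stop("code set file '", path, "' lacks a 'code' column", call. = FALSE)
  }
  bad <- which(is.na(df$code) | !nzchar(trimws(df$code)))
  if (length(bad)) {
    stop(sprintf("code set file '%s': blank code in row %d", path, bad[1L]),
         call. = FALSE)
  }
  cs <- codeset(df$code, name = name, match_mode = match_mode)
  message(sprintf("loaded code set '%s': %d codes (%s match)",
                  name, length(cs$codes), match_mode))
  cs
}

#' Match codes against a code set
#'
#' @param x character vector of codes to test.
#' @param cs a [codeset()].
#' @return Logical vector, one element per code in `x`.
#' @export
code_matches <- function(x, cs) {
  stopifnot(inherits(cs, "codeset"))
  x <- toupper(trimws(as.character(x)))
  if (!length(x)) return(logical(0))
  if (cs$match_mode == "exact") return(x %in% cs$codes)
  hit <- rep(FALSE, length(x))
  for (cd in cs$codes) hit <- hit | startsWith(x, cd)
  hit & !is.na(x)
}

#' @export
print.codeset <- function(x, ...) {
  cat(sprintf("<codeset '%s': %d codes, %s match>\n",
              x$name, length(x$codes), x$match_mode))
  invisible(x)
}

#' Construct a keyword rule
#'
#' A disjunction of conjunctive clauses over lower-cased substrings: the rule
#' is satisfied when, for at least one clause, every substring of that clause
#' occurs in the text. This mirrors how free-text procedure descriptions are
#' screened, e.g. feeding support is flagged by "nasogastric", or by
#' "gastrostomy" together with "feed", or "gastrostomy" together with "tube".
#'
#' @param clauses list of character vectors; each vector is one conjunctive
#'   clause of non-empty substrings.
#' @return An object of class `keyword_rule`.
#' @export
keyword_rule <- function(clauses) {
  if (!is.list(clauses) || !length(clauses)) {
    stop("a keyword rule needs at least one clause", call. = FALSE)
  }
  clauses <- lapply(clauses, function(cl) {
    cl <- tolower(trimws(as.character(cl)))
    if (!length(cl) || any(!nzchar(cl))) {
      stop("keyword clauses must contain non-empty substrings",
           call. = FALSE)
    }
    cl
  })
  structure(list(clauses = clauses), class = "keyword_rule")
}

#' Match text against a keyword rule
#'
#' Case-insensitive; `NA` or empty text never matches.
#'
#' @param text character vector.
#' @param rule a [keyword_rule()].
#' @return Logical vector, one element per text.
#' @export
#' @examples
#' keyword_match("Gastrostomy tube placement", feeding_keyword_rule())
keyword_match <- function(text, rule) {
  stopifnot(inherits(rule, "keyword_rule"))
  text <- tolower(as.character(text))
  if (!length(text)) return(logical(0))
  hit <- rep(FALSE, length(text))
  for (cl in rule$clauses) {
    clause_hit <- rep(TRUE, length(text))
    for (sub in cl) {
      clause_hit <- clause_hit & grepl(sub, text, fixed = TRUE)
    }
    hit <- hit | clause_hit
  }
  hit[is.na(text) | !nzchar(text)] <- FALSE
  hit
}

#' Default feeding-support keyword rule
#'
#' Flags procedure names describing nasogastric or gastrostomy feeding:
#' "nasogastric", or "gastrostomy" and "feed", or "gastrostomy" and "tube".
#'
#' @return A [keyword_rule()].
#' @export
feeding_keyword_rule <- function() {
  keyword_rule(list("nasogastric",
                    c("gastrostomy", "feed"),
                    c("gastrostomy", "tube")))
}

#' Default respiratory-support keyword rule
#'
#' Flags tracheostomy and mechanical ventilation (including CPAP) in
#' procedure names.
#'
#' @return A [keyword_rule()].
#' @export
respiratory_keyword_rule <- function() {
  keyword_rule(list("tracheostomy", "ventilat", "cpap"))
}

#' Construct a specialist taxonomy
#'
#' The set of specialty labels counted by the multiple-specialists criterion,
#' plus labels explicitly excluded from counting (by default Pediatric
#' Infectious Disease, since infections are mostly of environmental rather
#' than genetic etiology).
#'
#' @param included character vector of counted specialty labels.
#' @param excluded character vector of labels never counted.
#' @return An object of class `specialty_taxonomy`.
#' @export
specialty_taxonomy <- function(included, excluded = character(0)) {
  included <- unique(trimws(as.character(included)))
  excluded <- unique(trimws(as.character(excluded)))
  included <- included[nzchar(included)]
  if (!length(included)) {
    stop("specialty taxonomy needs at least one included label",
         call. = FALSE)
  }
  if (length(intersect(tolower(included), tolower(excluded)))) {
    stop("included and excluded specialty labels overlap", call. = FALSE)
  }
  structure(list(included = included, excluded = excluded),
            class = "specialty_taxonomy")
}

#' Default specialist taxonomy (20 included types)
#'
#' Twenty pediatric-relevant specialty types are counted; Pediatric
#' Infectious Disease is excluded. Labels are read from the taxonomy table
#' shipped with the package and can be overridden via [specialty_taxonomy()].
#'
#' @return A [specialty_taxonomy()].
#' @export
default_specialty_taxonomy <- function() {
  path <- system.file("extdata", "specialties.csv", package = "pheindex")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  specialty_taxonomy(df$label[df$status == "included"],
                     df$label[df$status == "excluded"])
}

#' Default vocabulary bundle
#'
#' Collects every code set, keyword rule and label the criteria engine needs:
#' feeding-support, developmental-delay, metabolic-disease and
#' respiratory-support code sets, the feeding and respiratory keyword rules,
#' the specialist taxonomy, the death-disposition terms, and the
#' developmental-pediatrics specialty label. The shipped code sets are
#' synthetic placeholders (see `inst/extdata/synthetic_codesets/`); supply
#' site-specific lists for real data.
#'
#' @param codeset_dir directory holding the four code-set CSVs; defaults to
#'   the synthetic sets shipped with the package.
#' @return A named list of class `pheindex_vocabulary`.
#' @export
default_vocabulary <- function(codeset_dir = NULL) {
  dir <- codeset_dir %||% system.file("extdata", "synthetic_codesets",
                                      package = "pheindex")
  load_quiet <- function(file, name) {
    suppressMessages(load_codeset(file.path(dir, file),
                                  match_mode = "prefix", name = name))
  }
  structure(list(
    feeding_codes = load_quiet("feeding_support.csv", "feeding_support"),
    developmental_delay_codes = load_quiet("developmental_delay.csv",
                                           "developmental_delay"),
    metabolic_codes = load_quiet("metabolic_disease.csv",
                                 "metabolic_disease"),
    respiratory_codes = load_quiet("respiratory_support.csv",
                                   "respiratory_support"),
    feeding_rule = feeding_keyword_rule(),
    respiratory_rule = respiratory_keyword_rule(),
    taxonomy = default_specialty_taxonomy(),
    death_dispositions = c("expired", "funeral home", "morgue",
                           "organ harvest"),
    developmental_pediatrics_label = "Developmental Pediatrics"
  ), class = "pheindex_vocabulary")
}
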