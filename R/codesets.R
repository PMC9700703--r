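#' ICD code normalization
#'
#' Normalizes raw ICD-9/ICD-10 codes as recorded in EHR diagnosis tables to
#' a canonical spelling: upper case, periods stripped, surrounding
#' whitespace removed. Dotted ("O14.1") and undotted ("O141") spellings of
#' the same code normalize identically, and normalization is idempotent.
#'
#' The coding system is inferred, not trusted: codes starting with a digit
#' are labeled ICD9; codes starting with "E" or "V" are ambiguous between
#' the two revisions and labeled UNKNOWN; any other leading letter implies
#' ICD10. The label is informational only and never affects matching.
#'
#' @param raw character vector of codes as recorded.
#' @return data.frame with columns `raw`, `normalized`, `system`.
#' @examples
#' normalize_icd(c("O14.1", "651.03", "o141"))
#' @export
normalize_icd <- function(raw) {
  raw <- as.character(raw)
  trimmed <- trimws(raw)
  bad <- is.na(trimmed) | trimmed == ""
  if (any(bad)) {
    stop(sprintf("empty or missing ICD code at record(s): %s",
                 paste(utils::head(which(bad), 10), collapse = ", ")),
         call. = FALSE)
  }
  normalized <- toupper(gsub(".", "", trimmed, fixed = TRUE))
  first <- substr(normalized, 1, 1)
  system <- ifelse(grepl("^[0-9]", first), "ICD9",
                   ifelse(first %in% c("E", "V"), "UNKNOWN", "ICD10"))
  data.frame(raw = raw, normalized = normalized, system = system,
             stringsAsFactors = FALSE)
}

#' Construct an ICD code set
#'
#' A code set is a named collection of normalized ICD codes (exact members)
#' and code prefixes defining an outcome or covariate phenotype. Members and
#' prefixes are normalized on construction.
#'
#' @param name set name, e.g. "preeclampsia".
#' @param role one of "OUTCOME" or "COVARIATE".
#' @param members character vector of exact codes (any ICD spelling).
#' @param prefix_members character vector of code prefixes; a diagnosis
#'   matches if any prefix is a leading substring of its normalized code.
#' @param prefix_matching set `FALSE` to disable prefix semantics for this
#'   set (prefixes are then ignored).
#' @return an object of class `codeset`.
#' @export
codeset <- function(name, role = c("OUTCOME", "COVARIATE"),
                    members = character(), prefix_members = character(),
                    prefix_matching = TRUE) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  norm <- function(x) {
    if (length(x) == 0) return(character())
    unique(normalize_icd(x)$normalized)
  }
  structure(list(name = name, role = role,
                 members = norm(members),
                 prefix_members = norm(prefix_members),
                 prefix_matching = isTRUE(prefix_matching)),
            class = "codeset")
}

#' @export
print.codeset <- function(x, ...) {
  cat(sprintf("<codeset %s (%s): %d exact, %d prefix%s>\n",
              x$name, x$role, length(x$members), length(x$prefix_members),
              if (x$prefix_matching) "" else ", prefix matching off"))
  invisible(x)
}

#' Match normalized codes against a code set
#'
#' A normalized code matches if it is an exact member or, when prefix
#' matching is enabled for the set, if any prefix member is a leading
#' substring. Exact membership is checked before prefixes. A set with no
#' members and no prefixes matches nothing.
#'
#' @param normalized character vector of normalized codes (see
#'   [normalize_icd()]).
#' @param cs a [codeset()].
#' @return logical vector, same length as `normalized`.
#' @export
code_matches <- function(normalized, cs) {
  stopifnot(inherits(cs, "codeset"))
  if (length(normalized) == 0) return(logical(0))
  hit <- normalized %in% cs$members
  if (cs$prefix_matching && length(cs$prefix_members) > 0) {
    todo <- which(!hit)
    for (p in cs$prefix_members) {
      if (length(todo) == 0) break
      m <- startsWith(normalized[todo], p)
      hit[todo[m]] <- TRUE
      todo <- todo[!m]
    }
  }
  hit
}

#' Read an ICD vocabulary file
#'
#' Loads code sets from a delimited file with one record per
#' `(set_name, role, code, is_prefix)`; `is_prefix` is 0/1 (or
#' TRUE/FALSE). Codes are validated and normalized on load.
#'
#' @param path path to a tab-delimited vocabulary file.
#' @return named list of [codeset()] objects (class `icd_vocabulary`).
#' @export
read_codesets <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("set_name", "role", "code", "is_prefix"), "vocabulary")
  df$is_prefix <- as.logical(as.integer(df$is_prefix))
  roles <- toupper(df$role)
  if (!all(roles %in% c("OUTCOME", "COVARIATE"))) {
    stop("vocabulary roles must be OUTCOME or COVARIATE", call. = FALSE)
  }
  sets <- lapply(split(seq_len(nrow(df)), df$set_name), function(idx) {
    r <- unique(roles[idx])
    if (length(r) != 1) {
      stop(sprintf("code set '%s' has conflicting roles", df$set_name[idx[1]]),
           call. = FALSE)
    }
    codeset(df$set_name[idx[1]], role = r,
            members = df$code[idx][!df$is_prefix[idx]],
            prefix_members = df$code[idx][df$is_prefix[idx]])
  })
  structure(sets, class = "icd_vocabulary")
}

# Subset a vocabulary by role, preserving order of first appearance.
vocab_by_role <- function(vocab, role) {
  vocab[vapply(vocab, function(cs) cs$role == role, logical(1))]
}
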