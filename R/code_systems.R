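#' Parse a 12-character MHLW drug code
#'
#' Japanese drug claims carry a 12-character code issued by the Ministry of
#' Health, Labour and Welfare (MHLW) whose positions encode the clinical
#' identity of the product: positions 1--4 are the 4-digit therapeutic class
#' (positions 1--3 being the coarser upper class), positions 5--7 the compound
#' number within the class, position 8 a capital letter for the dosage form,
#' position 9 a digit for the dose of a single unit, and positions 10--12 the
#' product number. The administration route is carried by the compound number:
#' 000--399 oral, 400--699 infusion, 700--999 external.
#'
#' For example, `"2171005F2021"` is an oral tablet: class 2171 (coronary
#' artery dilators, upper class 217 vasodilators), compound 005 (dilazep
#' hydrochloride hydrate), form F, dose digit 2, product 021.
#'
#' @param code A single 12-character code string.
#' @return An object of class `mhlw_code`: a list with fields `raw`, `class4`,
#'   `class3`, `compound`, `route` (one of `"oral"`, `"infusion"`,
#'   `"external"`), `form_letter`, `dose_digit`, `product`.
#' @examples
#' parse_mhlw_code("2171005F2021")
#' @seealso [drug_group_key()], [mhlw_route()]
#' @export
parse_mhlw_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stop("`code` must be a single character string")
  }
  if (nchar(code) != 12L) {
    stop(sprintf("malformed MHLW code '%s': expected 12 characters, got %d",
                 code, nchar(code)))
  }
  chars <- strsplit(code, "", fixed = TRUE)[[1L]]
  digit_pos <- c(1:7, 9:12)
  bad_digit <- digit_pos[!grepl("^[0-9]$", chars[digit_pos])]
  if (length(bad_digit) > 0L) {
    stop(sprintf("malformed MHLW code '%s': expected a digit at position %d, found '%s'",
                 code, bad_digit[1L], chars[bad_digit[1L]]))
  }
  if (!grepl("^[A-Z]$", chars[8L])) {
    stop(sprintf("malformed MHLW code '%s': expected an upper-case letter at position 8, found '%s'",
                 code, chars[8L]))
  }
  compound <- substr(code, 5L, 7L)
  structure(
    list(
      raw         = code,
      class4      = substr(code, 1L, 4L),
      class3      = substr(code, 1L, 3L),
      compound    = compound,
      route       = route_of_compound(as.integer(compound)),
      form_letter = chars[8L],
      dose_digit  = chars[9L],
      product     = substr(code, 10L, 12L)
    ),
    class = "mhlw_code"
  )
}

#' @export
print.mhlw_code <- function(x, ...) {
  cat(sprintf("<MHLW drug code %s>\n", x$raw))
  cat(sprintf("  class %s (upper %s), compound %s [%s], form %s, dose digit %s, product %s\n",
              x$class4, x$class3, x$compound, x$route, x$form_letter,
              x$dose_digit, x$product))
  invisible(x)
}

#' Reassemble a parsed MHLW code into its 12-character string
#'
#' @param x An `mhlw_code` object.
#' @return The raw 12-character code string.
#' @export
format_mhlw_code <- function(x) {
  stopifnot(inherits(x, "mhlw_code"))
  paste0(x$class4, x$compound, x$form_letter, x$dose_digit, x$product)
}

route_of_compound <- function(compound) {
  route <- rep(NA_character_, length(compound))
  route[compound >= 0L & compound <= 399L] <- "oral"
  route[compound >= 400L & compound <= 699L] <- "infusion"
  route[compound >= 700L & compound <= 999L] <- "external"
  route
}

#' Administration route of MHLW drug codes (vectorised)
#'
#' The route is encoded in the compound number (positions 5--7): 000--399
#' oral, 400--699 infusion, 700--999 external.
#'
#' @param codes Character vector of 12-character MHLW codes.
#' @return Character vector: `"oral"`, `"infusion"`, or `"external"`.
#' @export
mhlw_route <- function(codes) {
  route_of_compound(as.integer(substr(codes, 5L, 7L)))
}

#' Grouping key for a drug code: therapeutic class plus route
#'
#' Drugs sharing the top four digits of the MHLW code and the administration
#' route are placed in the same drug type; product, form, and dose are
#' ignored. This is the medication compilation used by the preprocessed
#' feature patterns (b) and (c).
#'
#' @param code An `mhlw_code` object (see [parse_mhlw_code()]) or a raw
#'   12-character code string.
#' @return A list with `system = "drug"` and `key`, e.g. `"2171:oral"`.
#' @examples
#' drug_group_key("2171005F2021")$key  # "2171:oral"
#' @export
drug_group_key <- function(code) {
  if (is.character(code)) code <- parse_mhlw_code(code)
  stopifnot(inherits(code, "mhlw_code"))
  list(system = "drug", key = paste0(code$class4, ":", code$route))
}

icd10_shape_ok <- function(codes) {
  grepl("^[A-Z][0-9A-Z]{2,3}$", codes)
}

#' Grouping key for an ICD-10 diagnosis code under a compilation scheme
#'
#' Scheme `"pattern_b"` compiles every diagnosis to its first two characters
#' (e.g. `"J359"` to `"J3"`) and *excludes* the nephrology category
#' (N0xx--N2xx) entirely; scheme `"pattern_c"` keeps nephrology codes,
#' compiled to their first three characters (e.g. `"N028"` to `"N02"`), and
#' agrees with `"pattern_b"` elsewhere.
#'
#' @param code Character vector of ICD-10 codes (letter plus 2--3
#'   alphanumerics).
#' @param scheme `"pattern_b"` or `"pattern_c"`.
#' @return Character vector of group keys; `NA` marks a code excluded by the
#'   scheme (the nephrology category under `"pattern_b"`).
#' @examples
#' icd10_group_key("J359", "pattern_b")  # "J3"
#' icd10_group_key("N028", "pattern_b")  # NA (nephrology excluded)
#' icd10_group_key("N028", "pattern_c")  # "N02"
#' @export
icd10_group_key <- function(code, scheme = c("pattern_b", "pattern_c")) {
  scheme <- match.arg(scheme)
  ok <- icd10_shape_ok(code)
  if (any(!ok)) {
    stop(sprintf("malformed ICD-10 code '%s': expected a letter followed by 2-3 alphanumerics",
                 code[!ok][1L]))
  }
  nephro <- substr(code, 1L, 2L) %in% c("N0", "N1", "N2")
  key <- substr(code, 1L, 2L)
  if (scheme == "pattern_b") {
    key[nephro] <- NA_character_
  } else {
    key[nephro] <- substr(code[nephro], 1L, 3L)
  }
  key
}

#' Match a claim code against a wildcard pattern
#'
#' Patterns use literal characters plus lower-case `"x"` as a
#' single-character wildcard, in the style of code masks such as `"N02x"` or
#' `"2171xxxxxxx"`. A pattern shorter than the code is matched as a prefix
#' (implicit trailing wildcards); a pattern longer than the code matches only
#' if the surplus pattern characters are all wildcards, so `"N02x"` matches
#' both `"N02"` and `"N028"`.
#'
#' @param pattern A single non-empty pattern string.
#' @param code Character vector of codes to test.
#' @return Logical vector, one element per code.
#' @examples
#' matches_code_pattern("N02x", c("N028", "N031"))  # TRUE FALSE
#' @export
matches_code_pattern <- function(pattern, code) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern) ||
      is.na(pattern)) {
    stop("`pattern` must be a single non-empty string")
  }
  ok <- rep(TRUE, length(code))
  for (i in seq_len(nchar(pattern))) {
    pc <- substr(pattern, i, i)
    if (pc == "x") next
    ok <- ok & substr(code, i, i) == pc
  }
  ok
}
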