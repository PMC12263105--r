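#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter algorithm
#' (suffix-stripping in five ordered steps gated by the consonant-vowel
#' "measure" of the remaining stem). This is the normalization applied to
#' dictionary terms, abstract text and annotation keys alike, so that
#' inflectional variants ("stressors", "stressor") collapse to one token.
#'
#' Words of one or two characters are returned unchanged. Characters outside
#' a-z (digits, Greek letters) are treated as consonants and never stripped,
#' which leaves gene-symbol-like tokens ("tp53") intact.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("stressors", "apoptosis", "signaling", "relational"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  if (length(words) == 0L) return(character(0))
  uw <- unique(words)
  st <- vapply(uw, .porter1, character(1), USE.NAMES = FALSE)
  st[match(words, uw)]
}

.p_vowels <- c("a", "e", "i", "o", "u")

# consonant profile: TRUE where letter acts as a consonant; 'y' is a
# consonant at word start or after a vowel, a vowel after a consonant
.p_cons <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% .p_vowels) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# measure m of [C](VC)^m[V]: number of vowel-run -> consonant-run transitions
.p_m <- function(w) {
  if (!nzchar(w)) return(0L)
  r <- rle(.p_cons(strsplit(w, "", fixed = TRUE)[[1]]))$values
  if (length(r) < 2L) return(0L)
  sum(!r[-length(r)] & r[-1L])
}

.p_has_vowel <- function(w) {
  nzchar(w) && any(!.p_cons(strsplit(w, "", fixed = TRUE)[[1]]))
}

.p_ends_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  ch[n] == ch[n - 1L] && .p_cons(ch)[n]
}

# *o: stem ends consonant-vowel-consonant and final consonant is not w, x, y
.p_ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  cons <- .p_cons(ch)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(ch[n] %in% c("w", "x", "y"))
}

.p_ends <- function(w, suf) {
  nw <- nchar(w); ns <- nchar(suf)
  nw > ns && substr(w, nw - ns + 1L, nw) == suf
}

.p_chop <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))

# longest-matching-suffix rule application for steps 2-4; once a suffix
# matches, its condition decides and no shorter suffix is tried
.p_rules <- function(w, rules, min_m) {
  sufs <- vapply(rules, `[[`, character(1), 1L)
  hit <- which(vapply(sufs, function(s) .p_ends(w, s), logical(1)))
  if (!length(hit)) return(w)
  best <- hit[which.max(nchar(sufs[hit]))]
  stem <- .p_chop(w, sufs[best])
  if (.p_m(stem) > min_m) paste0(stem, rules[[best]][2L]) else w
}

.p_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble")
)

.p_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.p_step4_sufs <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.porter1 <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a: plurals
  if (.p_ends(w, "sses")) {
    w <- .p_chop(w, "es")
  } else if (.p_ends(w, "ies")) {
    w <- paste0(.p_chop(w, "ies"), "i")
  } else if (!.p_ends(w, "ss") && .p_ends(w, "s")) {
    w <- .p_chop(w, "s")
  }

  # step 1b: -eed / -ed / -ing
  fired <- FALSE
  if (.p_ends(w, "eed")) {
    if (.p_m(.p_chop(w, "eed")) > 0L) w <- .p_chop(w, "d")
  } else if (.p_ends(w, "ed") && .p_has_vowel(.p_chop(w, "ed"))) {
    w <- .p_chop(w, "ed"); fired <- TRUE
  } else if (.p_ends(w, "ing") && .p_has_vowel(.p_chop(w, "ing"))) {
    w <- .p_chop(w, "ing"); fired <- TRUE
  }
  if (fired) {
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_ends_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.p_m(w) == 1L && .p_ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: terminal y -> i when the stem holds a vowel
  if (.p_ends(w, "y") && .p_has_vowel(.p_chop(w, "y"))) {
    w <- paste0(.p_chop(w, "y"), "i")
  }

  # steps 2-3: derivational suffix mapping (m > 0)
  w <- .p_rules(w, .p_step2_rules, 0L)
  w <- .p_rules(w, .p_step3_rules, 0L)

  # step 4: suffix deletion (m > 1); -ion needs stem ending in s or t
  sufs <- .p_step4_sufs
  hit <- which(vapply(sufs, function(s) .p_ends(w, s), logical(1)))
  if (length(hit)) {
    best <- hit[which.max(nchar(sufs[hit]))]
    stem <- .p_chop(w, sufs[best])
    ok <- .p_m(stem) > 1L
    if (ok && sufs[best] == "ion") {
      ok <- substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
    }
    if (ok) w <- stem
  }

  # step 5a: drop terminal e
  if (.p_ends(w, "e")) {
    stem <- .p_chop(w, "e")
    m <- .p_m(stem)
    if (m > 1L || (m == 1L && !.p_ends_cvc(stem))) w <- stem
  }

  # step 5b: -ll -> -l when m > 1
  if (.p_m(w) > 1L && .p_ends_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1L, nchar(w) - 1L)
  }

  w
}
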