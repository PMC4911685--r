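#' Porter stemming algorithm
#'
#' Reduces English words to their stems using the classic Porter (1980)
#' suffix-stripping algorithm, the normalization step used throughout the
#' retrieval and concept-association pipelines (e.g. "body" -> "bodi",
#' "circumference" -> "circumfer").
#'
#' Words shorter than three letters are returned unchanged, as in the
#' original algorithm description.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("body", "mass", "circumference"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  u <- unique(words)
  stems <- vapply(u, .porter_one, character(1), USE.NAMES = TRUE)
  unname(stems[words])
}

# TRUE at position i when the letter is a consonant: not a/e/i/o/u, and a
# "y" counts as a consonant only when not preceded by a consonant.
.porter_cons <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cons <- logical(n)
  for (i in seq_len(n)) {
    cons[i] <- if (ch[i] %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (ch[i] == "y") {
      i == 1L || !cons[i - 1L]
    } else {
      TRUE
    }
  }
  cons
}

# The measure m of a word: number of VC blocks in [C](VC)^m[V].
.porter_m <- function(word) {
  if (!nzchar(word)) return(0L)
  runs <- rle(.porter_cons(word))$values
  sum(!runs[-length(runs)] & runs[-1L])
}

.porter_has_vowel <- function(word) {
  nzchar(word) && any(!.porter_cons(word))
}

# Ends in a double consonant (same letter twice).
.porter_ends_cc <- function(word) {
  n <- nchar(word)
  n >= 2L &&
    substr(word, n, n) == substr(word, n - 1L, n - 1L) &&
    .porter_cons(word)[n]
}

# Ends consonant-vowel-consonant where the final consonant is not w, x or y.
.porter_ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- .porter_cons(word)
  cons[n - 2L] && !cons[n - 1L] && cons[n] &&
    !(substr(word, n, n) %in% c("w", "x", "y"))
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# Apply the first (longest) matching rule of a step-2/3/4 style table.
# `rules` is a data.frame with columns suffix, replacement; `cond` takes the
# stem and returns TRUE when the rule may fire. Once a suffix matches, no
# shorter suffix is tried (single-rule-per-step convention).
.porter_rules <- function(word, rules, cond) {
  for (i in order(-nchar(rules$suffix))) {
    suf <- rules$suffix[i]
    if (endsWith(word, suf)) {
      stem <- .chop(word, nchar(suf))
      if (cond(stem)) word <- paste0(stem, rules$replacement[i])
      return(word)
    }
  }
  word
}

.porter_step2_rules <- data.frame(
  suffix = c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
             "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
             "iveness", "fulness", "ousness", "aliti", "iviti", "biliti"),
  replacement = c("ate", "tion", "ence", "ance", "ize", "able", "al",
                  "ent", "e", "ous", "ize", "ate", "ate", "al",
                  "ive", "ful", "ous", "al", "ive", "ble"),
  stringsAsFactors = FALSE
)

.porter_step3_rules <- data.frame(
  suffix = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
  replacement = c("ic", "", "al", "ic", "ic", "", ""),
  stringsAsFactors = FALSE
)

.porter_step4_suffixes <- c("al", "ance", "ence", "er", "ic", "able", "ible",
                            "ant", "ement", "ment", "ent", "ion", "ou", "ism",
                            "ate", "iti", "ous", "ive", "ize")

.porter_one <- function(word) {
  if (nchar(word) < 3L) return(word)

  # Step 1a: plurals
  if (endsWith(word, "sses")) {
    word <- .chop(word, 2L)
  } else if (endsWith(word, "ies")) {
    word <- paste0(.chop(word, 3L), "i")
  } else if (!endsWith(word, "ss") && endsWith(word, "s")) {
    word <- .chop(word, 1L)
  }

  # Step 1b: -eed / -ed / -ing
  fired <- FALSE
  if (endsWith(word, "eed")) {
    stem <- .chop(word, 3L)
    if (.porter_m(stem) > 0L) word <- .chop(word, 1L)
  } else if (endsWith(word, "ed") && .porter_has_vowel(.chop(word, 2L))) {
    word <- .chop(word, 2L)
    fired <- TRUE
  } else if (endsWith(word, "ing") && .porter_has_vowel(.chop(word, 3L))) {
    word <- .chop(word, 3L)
    fired <- TRUE
  }
  if (fired) {
    if (endsWith(word, "at") || endsWith(word, "bl") || endsWith(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_ends_cc(word) &&
               !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
      word <- .chop(word, 1L)
    } else if (.porter_m(word) == 1L && .porter_ends_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c: terminal y -> i when the stem has a vowel
  if (endsWith(word, "y") && .porter_has_vowel(.chop(word, 1L))) {
    word <- paste0(.chop(word, 1L), "i")
  }

  # Steps 2 and 3: double and simple suffixes, condition m(stem) > 0
  word <- .porter_rules(word, .porter_step2_rules, function(s) .porter_m(s) > 0L)
  word <- .porter_rules(word, .porter_step3_rules, function(s) .porter_m(s) > 0L)

  # Step 4: strip residual suffixes when m(stem) > 1; -ion additionally
  # requires the stem to end in s or t
  for (i in order(-nchar(.porter_step4_suffixes))) {
    suf <- .porter_step4_suffixes[i]
    if (endsWith(word, suf)) {
      stem <- .chop(word, nchar(suf))
      ok <- .porter_m(stem) > 1L
      if (ok && suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- last %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # Step 5a: drop terminal e
  if (endsWith(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_ends_cvc(stem))) word <- stem
  }
  # Step 5b: -ll -> -l when m > 1
  if (.porter_m(word) > 1L && .porter_ends_cc(word) && endsWith(word, "l")) {
    word <- .chop(word, 1L)
  }

  word
}
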