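# Porter stemmer (the classic 1980 algorithm), implemented directly because
# the surrounding analyses need stems like "vaccin" for "vaccine" /
# "vaccinated" / "vaccination" and prefix matching on stemmed tokens.
#
# Words are lower-case a-z; tokens containing digits are returned
# unchanged, a trailing "'s" is removed and other apostrophes dropped
# before stemming. Words of length <= 2 are never changed.

.p_vowels <- c("a", "e", "i", "o", "u")

# consonant flags for a character vector of single letters:
# y is a consonant at position 1 or after a vowel, a vowel after a consonant
.p_cons <- function(chars) {
  cons <- !(chars %in% .p_vowels)
  for (i in seq_along(chars))
    if (chars[i] == "y" && i > 1) cons[i] <- !cons[i - 1]
  cons
}

# the measure m of a stem: number of vowel-consonant sequences
.p_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  v <- rle(.p_cons(strsplit(stem, "", fixed = TRUE)[[1]]))$values
  if (length(v) < 2) return(0L)
  sum(!v[-length(v)] & v[-1])
}

.p_has_vowel <- function(stem) {
  nzchar(stem) && any(!.p_cons(strsplit(stem, "", fixed = TRUE)[[1]]))
}

# stem ends with a double consonant
.p_dbl <- function(w) {
  n <- nchar(w)
  if (n < 2) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  ch[n] == ch[n - 1] && .p_cons(ch)[n]
}

# stem ends consonant-vowel-consonant, final consonant not w, x or y
.p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  cons <- .p_cons(ch)
  cons[n - 2] && !cons[n - 1] && cons[n] && !(ch[n] %in% c("w", "x", "y"))
}

.p_drop <- function(w, k) substr(w, 1, nchar(w) - k)

# steps 2-4 share one mechanism: take the longest matching suffix from the
# table; if the stem condition holds, replace; either way stop looking.
.p_table_step <- function(w, suffixes, repls, cond) {
  ord <- order(nchar(suffixes), decreasing = TRUE)
  for (i in ord) {
    sfx <- suffixes[i]
    if (endsWith(w, sfx) && nchar(w) > nchar(sfx)) {
      stem <- .p_drop(w, nchar(sfx))
      if (cond(stem, sfx)) return(paste0(stem, repls[i]))
      return(w)
    }
  }
  w
}

# step 1a with the English-stemmer refinements: "us"/"ss" endings are left
# alone ("serious", "virus") and a bare "s" is only dropped when a vowel
# occurs before the letter preceding it ("gas" survives, "cats" -> "cat")
.p_step1a <- function(w) {
  if (endsWith(w, "sses")) return(.p_drop(w, 2))
  if (endsWith(w, "ies"))  return(.p_drop(w, 2))
  if (endsWith(w, "ss") || endsWith(w, "us")) return(w)
  if (endsWith(w, "s")) {
    stem <- .p_drop(w, 1)
    if (nchar(stem) >= 2 && .p_has_vowel(.p_drop(stem, 1))) return(stem)
  }
  w
}

.p_step1b <- function(w) {
  if (endsWith(w, "eed")) {
    if (.p_m(.p_drop(w, 3)) > 0) return(.p_drop(w, 1))
    return(w)
  }
  removed <- FALSE
  if (endsWith(w, "ed") && .p_has_vowel(.p_drop(w, 2))) {
    w <- .p_drop(w, 2); removed <- TRUE
  } else if (endsWith(w, "ing") && .p_has_vowel(.p_drop(w, 3))) {
    w <- .p_drop(w, 3); removed <- TRUE
  }
  if (removed) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_dbl(w) && !endsWith(w, "l") && !endsWith(w, "s") &&
               !endsWith(w, "z")) {
      w <- .p_drop(w, 1)
    } else if (.p_m(w) == 1 && .p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

# revised (English-stemmer) step 1c: y -> i only when preceded by a
# consonant that is not the first letter, so "stay" and "say" survive
# while "happy" -> "happi" and "worry" -> "worri"
.p_step1c <- function(w) {
  n <- nchar(w)
  if (n >= 3 && endsWith(w, "y")) {
    prev <- substr(w, n - 1, n - 1)
    if (!(prev %in% .p_vowels)) return(paste0(.p_drop(w, 1), "i"))
  }
  w
}

.p_step2_sfx <- c("ational", "tional", "enci", "anci", "izer", "abli",
                  "alli", "entli", "eli", "ousli", "ization", "ation",
                  "ator", "alism", "iveness", "fulness", "ousness",
                  "aliti", "iviti", "biliti")
.p_step2_rep <- c("ate", "tion", "ence", "ance", "ize", "able",
                  "al", "ent", "e", "ous", "ize", "ate",
                  "ate", "al", "ive", "ful", "ous",
                  "al", "ive", "ble")

.p_step3_sfx <- c("icate", "ative", "alize", "iciti", "ical", "ful", "ness")
.p_step3_rep <- c("ic", "", "al", "ic", "ic", "", "")

.p_step4_sfx <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                  "ement", "ment", "ent", "ion", "ou", "ism", "ate",
                  "iti", "ous", "ive", "ize")

.p_step5a <- function(w) {
  if (endsWith(w, "e")) {
    stem <- .p_drop(w, 1)
    m <- .p_m(stem)
    if (m > 1 || (m == 1 && !.p_cvc(stem))) return(stem)
  }
  w
}

.p_step5b <- function(w) {
  if (.p_m(w) > 1 && .p_dbl(w) && endsWith(w, "l")) return(.p_drop(w, 1))
  w
}

# words the suffix rules would mangle; kept invariant as in the standard
# English-stemmer exception list
.p_invariant <- c("sky", "news", "howe", "atlas", "cosmos", "bias", "andes")

porter_stem_word <- function(w) {
  if (grepl("'s$", w)) w <- sub("'s$", "", w)
  w <- gsub("'", "", w, fixed = TRUE)
  if (nchar(w) <= 2 || grepl("[^a-z]", w) || w %in% .p_invariant) return(w)
  w <- .p_step1a(w)
  w <- .p_step1b(w)
  w <- .p_step1c(w)
  w <- .p_table_step(w, .p_step2_sfx, .p_step2_rep,
                     function(stem, sfx) .p_m(stem) > 0)
  w <- .p_table_step(w, .p_step3_sfx, .p_step3_rep,
                     function(stem, sfx) .p_m(stem) > 0)
  w <- .p_table_step(w, .p_step4_sfx, rep("", length(.p_step4_sfx)),
                     function(stem, sfx) {
                       if (sfx == "ion" &&
                           !(endsWith(stem, "s") || endsWith(stem, "t")))
                         return(FALSE)
                       .p_m(stem) > 1
                     })
  w <- .p_step5a(w)
  .p_step5b(w)
}

#' Porter stem of word tokens
#'
#' Applies the classic Porter suffix-stripping algorithm to lower-case word
#' tokens (`"vaccination"` becomes `"vaccin"`, `"staying"` becomes
#' `"stay"`). Tokens containing digits are returned unchanged; a trailing
#' `'s` is removed before stemming.
#'
#' @param tokens Character vector of lower-case tokens.
#' @return Character vector of stems, same length.
#' @export
#' @examples
#' porter_stem(c("vaccines", "vaccinated", "worrying", "happiness"))
porter_stem <- function(tokens) {
  if (!is.character(tokens)) abort("`tokens` must be a character vector.")
  if (length(tokens) == 0) return(character(0))
  u <- unique(tokens)
  stems <- vapply(u, porter_stem_word, character(1), USE.NAMES = FALSE)
  stems[match(tokens, u)]
}
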