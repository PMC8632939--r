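# Shared vocabulary of the package: the nine emotion scales, the Likert
# bounds, and the packaged English stopword snapshot.

#' The nine emotion scales
#'
#' Names of the nine emotions rated on a 1-9 Likert scale in both waves,
#' in canonical order. `worry` is rated but excluded from the forced-choice
#' "which emotion best describes your feeling" item.
#'
#' @return Character vector of length nine.
#' @export
#' @examples
#' emotion_names()
emotion_names <- function() {
  c("anger", "anxiety", "desire", "disgust", "fear",
    "happiness", "relaxation", "sadness", "worry")
}

.likert_min <- 1L
.likert_max <- 9L

#' English stopword snapshot
#'
#' A 175-entry snapshot of the Snowball English stopword list, used by the
#' default English-language heuristic and by n-gram preprocessing. The list
#' is swappable: every consumer takes a `stopwords` argument.
#'
#' @return Character vector of lower-case stopwords.
#' @export
stopwords_en <- function() .stopwords_en

.stopwords_en <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves",
  "you", "your", "yours", "yourself", "yourselves",
  "he", "him", "his", "himself", "she", "her", "hers", "herself",
  "it", "its", "itself", "they", "them", "their", "theirs", "themselves",
  "what", "which", "who", "whom", "this", "that", "these", "those",
  "am", "is", "are", "was", "were", "be", "been", "being", "will",
  "have", "has", "had", "having", "do", "does", "did", "doing",
  "would", "should", "could", "ought",
  "i'm", "you're", "he's", "she's", "it's", "we're", "they're",
  "i've", "you've", "we've", "they've",
  "i'd", "you'd", "he'd", "she'd", "we'd", "they'd",
  "i'll", "you'll", "he'll", "she'll", "we'll", "they'll",
  "isn't", "aren't", "wasn't", "weren't", "hasn't", "haven't", "hadn't",
  "doesn't", "don't", "didn't", "won't", "wouldn't", "shan't", "shouldn't",
  "can't", "cannot", "couldn't", "mustn't",
  "let's", "that's", "who's", "what's", "here's", "there's",
  "when's", "where's", "why's", "how's",
  "a", "an", "the", "and", "but", "if", "or", "because", "as",
  "until", "while", "of", "at", "by", "for", "with", "about",
  "against", "between", "into", "through", "during", "before", "after",
  "above", "below", "to", "from", "up", "down", "in", "out", "on", "off",
  "over", "under", "again", "further", "then", "once",
  "here", "there", "when", "where", "why", "how",
  "all", "any", "both", "each", "few", "more", "most", "other",
  "some", "such", "no", "nor", "not", "only", "own", "same",
  "so", "than", "too", "very"
)
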