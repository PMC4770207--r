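#' Parse a dot-bracket string into a pair table
#'
#' @param db dot-bracket string (`.` unpaired, `(`/`)` paired; non-crossing).
#' @return integer vector `pt` with `pt[i] = j` if positions i and j pair,
#'   0 if unpaired (1-based).
#' @export
db_pairs <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (length(ch) && any(!ch %in% c(".", "(", ")"))) {
    stop("dot-bracket may contain only '.', '(' and ')'")
  }
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  pt
}

#' Convert a pair table back to dot-bracket
#'
#' @param pt integer pair table as returned by [db_pairs()].
#' @return dot-bracket string.
#' @export
pairs_db <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

# two-column matrix of pairs (i < j) from a pair table
.pt_pairs <- function(pt) {
  i <- which(pt > seq_along(pt))
  cbind(i = i, j = pt[i])
}
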