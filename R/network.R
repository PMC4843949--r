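#' Five-source mismatch-negativity network
#'
#' The standard MMN source model: bilateral primary auditory cortices (A1),
#' bilateral superior temporal gyri (STG) and right inferior frontal gyrus
#' (rIFG), with forward connections lA1->lSTG, rA1->rSTG, rSTG->rIFG,
#' reciprocal backward connections, lateral connections lA1<->rA1 and
#' lSTG<->rSTG, and exogenous auditory input entering bilateral A1.
#' Prior source locations are in MNI millimetres.
#'
#' @return an object of class `mmn_network`: list with `sources` (data.frame
#'   of name/x/y/z), `forward`, `backward`, `lateral` (2-column from/to
#'   matrices of source indices) and `input_targets` (source indices).
#' @export
mmn_network <- function() {
  sources <- data.frame(
    name = c("lA1", "rA1", "lSTG", "rSTG", "rIFG"),
    x = c(-42, 46, -61, 59, 46),
    y = c(-22, -14, -32, -25, 20),
    z = c(7, 8, 8, 8, 8),
    stringsAsFactors = FALSE
  )
  edges <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("from", "to")
    m
  }
  net <- list(
    sources = sources,
    # forward: ascending, from sp of source to ss/dp of target
    forward = edges(1, 3, 2, 4, 4, 5),
    # backward: reciprocal descending connections
    backward = edges(3, 1, 4, 2, 5, 4),
    # lateral: homologous interhemispheric links (each row one direction)
    lateral = edges(1, 2, 2, 1, 3, 4, 4, 3),
    input_targets = c(1, 2)
  )
  class(net) <- "mmn_network"
  net
}

#' @export
print.mmn_network <- function(x, ...) {
  cat("MMN source network:", nrow(x$sources), "sources\n")
  nm <- x$sources$name
  cat(" forward :", paste(nm[x$forward[, 1]], "->", nm[x$forward[, 2]],
                          collapse = ", "), "\n")
  cat(" backward:", paste(nm[x$backward[, 1]], "->", nm[x$backward[, 2]],
                          collapse = ", "), "\n")
  cat(" lateral :", paste(nm[x$lateral[, 1]], "->", nm[x$lateral[, 2]],
                          collapse = ", "), "\n")
  cat(" input   :", paste(nm[x$input_targets], collapse = ", "), "\n")
  invisible(x)
}

source_index <- function(network, name) {
  i <- match(name, network$sources$name)
  if (any(is.na(i))) {
    stop("unknown source name(s): ",
         paste(name[is.na(i)], collapse = ", "))
  }
  i
}
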