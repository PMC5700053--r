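#' Signed connectivity matrix
#'
#' The model's estimable parameter set: an N x N real matrix whose entry
#' `(v, w)` is the coupling strength of region `w` on region `v` multiplied
#' by the attitude sign of the pair (+1 emulative, -1 non-emulative). The
#' non-negative weight matrix is `abs(entries)` and the attitude is
#' `sign(entries)`. The matrix is generally asymmetric (directed influences)
#' and may carry self loops on the diagonal.
#'
#' @param entries Square numeric matrix of signed couplings; row `v`,
#'   column `w` is the influence OF `w` ON `v`.
#' @param labels Optional character vector of node labels; defaults to the
#'   matrix dimnames or `n1..nN`.
#' @return A numeric matrix of class `signed_connectivity` with node labels
#'   as dimnames.
#' @export
#' @examples
#' signed_connectivity(matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE))
signed_connectivity <- function(entries, labels = NULL) {
  if (!is.matrix(entries) || !is.numeric(entries)) {
    stop("connectivity entries must be a numeric matrix", call. = FALSE)
  }
  if (nrow(entries) != ncol(entries)) {
    stop("connectivity matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(entries))) {
    stop("connectivity entries must be finite", call. = FALSE)
  }
  n <- nrow(entries)
  if (is.null(labels)) {
    labels <- rownames(entries)
    if (is.null(labels)) labels <- paste0("n", seq_len(n))
  }
  if (length(labels) != n || anyDuplicated(labels)) {
    stop("need ", n, " unique node labels", call. = FALSE)
  }
  dimnames(entries) <- list(labels, labels)
  class(entries) <- c("signed_connectivity", class(matrix()))
  entries
}

#' @export
print.signed_connectivity <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<signed_connectivity> %d nodes, %d nonzero couplings (%d self loops)\n",
              n, sum(x != 0), sum(diag(unclass(x)) != 0)))
  print(unclass(x), ...)
  invisible(x)
}

#' Non-negative coupling weights of a signed connectivity matrix
#' @param conn A [signed_connectivity()] matrix.
#' @return The elementwise absolute value (adjacency weights).
#' @export
coupling_weights <- function(conn) abs(unclass(conn))

#' Attitude signs of a signed connectivity matrix
#' @param conn A [signed_connectivity()] matrix.
#' @return Matrix of -1/0/+1 attitudes (0 where there is no edge).
#' @export
attitude_signs <- function(conn) sign(unclass(conn))

node_labels <- function(conn) rownames(conn)

as_conn_matrix <- function(conn) {
  m <- unclass(conn)
  class(m) <- class(matrix())
  m
}
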