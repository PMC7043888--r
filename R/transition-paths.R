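#' Generate image-transition paths
#'
#' Builds randomized Eulerian circuits over the complete directed graph on
#' `n_images` nodes including self-loops. Each path visits every ordered
#' image pair (i, j) -- including the `n_images` same-to-same (catch)
#' transitions -- exactly once, giving `n_images^2` transitions and a path
#' of length `n_images^2 + 1`, closed (first node equals last). Sessions
#' draw a path at random and advance one transition per trial, which makes
#' the catch frequency exactly `n_images / n_images^2` (12.5% for 8 images)
#' per completed path.
#'
#' Construction is a randomized Hierholzer traversal: every node's out-edge
#' list is a random permutation of all targets, and the circuit is the
#' reversed pop order of a depth-first edge walk. The complete digraph with
#' self-loops has equal in- and out-degree everywhere, so a circuit always
#' exists.
#'
#' @param n_paths Number of paths to generate.
#' @param n_images Number of images (nodes).
#' @return A list of integer vectors (image ids in `0:(n_images-1)`), each
#'   of length `n_images^2 + 1`.
#' @examples
#' set.seed(1)
#' p <- generate_transition_paths(2, 4)[[1]]
#' length(p)  # 17
#' @export
generate_transition_paths <- function(n_paths, n_images) {
  n_paths <- check_count(n_paths, "n_paths")
  if (check_count(n_images, "n_images") < 1L) {
    stop("'n_images' must be >= 1", call. = FALSE)
  }
  k <- as.integer(n_images)
  lapply(seq_len(n_paths), function(i) euler_circuit(k) - 1L)
}

# randomized Hierholzer circuit on the complete digraph with self-loops,
# 1-based nodes
euler_circuit <- function(k) {
  if (k == 1L) return(c(1L, 1L))
  # targets[[v]]: random order in which v's out-edges are consumed
  targets <- lapply(seq_len(k), function(v) sample.int(k))
  ptr <- integer(k)                     # edges consumed per node
  stack <- integer(k * k + 1L)
  stack[1L] <- sample.int(k, 1L)
  top <- 1L
  circuit <- integer(k * k + 1L)
  nc <- 0L
  while (top > 0L) {
    v <- stack[top]
    if (ptr[v] < k) {
      ptr[v] <- ptr[v] + 1L
      top <- top + 1L
      stack[top] <- targets[[v]][ptr[v]]
    } else {
      nc <- nc + 1L
      circuit[nc] <- v
      top <- top - 1L
    }
  }
  rev(circuit[seq_len(nc)])
}

# rotate a closed circuit so it starts at `node` (0-based ids); used when a
# session chains a fresh path onto the currently displayed image
rotate_circuit <- function(path, node) {
  idx <- match(node, path)
  if (is.na(idx) || idx == 1L) return(path)
  n <- length(path)
  c(path[idx:(n - 1L)], path[1L:idx])
}
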