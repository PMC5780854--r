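# Internal helpers shared across modules.

# Locale-independent character sort, so serialized outputs are byte-stable.
.sortC <- function(x) {
  if (!length(x)) return(character(0))
  sort(x, method = "radix")
}

.orderC <- function(...) order(..., method = "radix")

# Find one directed cycle in an edge set, or NULL if acyclic.
# Iterative colored DFS; returns the cycle as a vector of node ids with the
# starting node repeated at the end.
.findCycle <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(NULL)
  adj <- split(edges$parent, factor(edges$child, levels = nodes))
  color <- setNames(rep(0L, length(nodes)), nodes)  # 0 white, 1 gray, 2 black
  parentOf <- setNames(rep(NA_character_, length(nodes)), nodes)
  for (start in nodes) {
    if (color[[start]] != 0L) next
    stack <- list(list(node = start, i = 1L))
    color[[start]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$node]]
      if (is.null(nbrs)) nbrs <- character()
      if (top$i <= length(nbrs)) {
        v <- nbrs[[top$i]]
        stack[[length(stack)]]$i <- top$i + 1L
        if (color[[v]] == 1L) {
          # walk back up the gray chain to reconstruct the cycle
          cyc <- top$node
          while (cyc[[1L]] != v) cyc <- c(parentOf[[cyc[[1L]]]], cyc)
          return(c(cyc, v))
        } else if (color[[v]] == 0L) {
          color[[v]] <- 1L
          parentOf[[v]] <- top$node
          stack[[length(stack) + 1L]] <- list(node = v, i = 1L)
        }
      } else {
        color[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

# data.frame constructor that never creates factors or mangles names
.df <- function(...) data.frame(..., stringsAsFactors = FALSE)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
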