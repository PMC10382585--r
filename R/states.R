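#' State space of a progressive multistate disease model
#'
#' A state space is an ordered set of state labels together with the subset
#' of absorbing states (states that, once entered, are never left).  The
#' default space describes the natural history of essential thrombocythemia
#' (ET) and prefibrotic primary myelofibrosis (pre-PMF): all patients start
#' at diagnosis and may pass through thrombosis, overt myelofibrosis (MF)
#' and/or blast phase (BP) before death, the sole absorbing state.
#'
#' @param states character vector of unique, non-empty state labels.
#' @param absorbing character vector, a non-empty subset of `states`.
#' @return An object of class `"state_space"`: a list with elements
#'   `states` and `absorbing`.
#' @examples
#' state_space()
#' state_space(c("Healthy", "Ill", "Dead"), absorbing = "Dead")
#' @export
state_space <- function(states = c("Diagnosis", "Thrombosis", "OvertMF",
                                   "BlastPhase", "Death"),
                        absorbing = "Death") {
  states <- as.character(states)
  absorbing <- as.character(absorbing)
  if (anyDuplicated(states) || any(!nzchar(states)))
    stop("state labels must be unique and non-empty")
  if (length(absorbing) < 1L)
    stop("at least one absorbing state is required")
  if (!all(absorbing %in% states))
    stop("absorbing states must be a subset of 'states'")
  structure(list(states = states, absorbing = absorbing),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space:", paste(x$states, collapse = " -> "), "\n")
  cat("Absorbing:  ", paste(x$absorbing, collapse = ", "), "\n")
  invisible(x)
}

#' Directed transition structure over a state space
#'
#' The transition structure is the directed graph that indexes every
#' computation in the package: each edge `(from, to)` carries an integer
#' transition id `1..K`.  The default structure has the ten transitions of
#' the progressive ET / pre-PMF model:
#' Diagnosis to each of Thrombosis, OvertMF, BlastPhase, Death;
#' Thrombosis to OvertMF, BlastPhase, Death; OvertMF to BlastPhase, Death;
#' and BlastPhase to Death.  Self-edges and edges out of absorbing states
#' are rejected, and the graph must be acyclic (a progressive model: no
#' state can be revisited).
#'
#' @param space a [state_space()].
#' @param edges a two-column character matrix or data.frame of
#'   `(from, to)` label pairs; rows are assigned transition ids in order.
#' @return An object of class `"transition_structure"`: a list with
#'   `space`, and `edges` (a data.frame with columns
#'   `trans`, `from`, `to`).
#' @examples
#' ts <- transition_structure()
#' ts$edges
#' @export
transition_structure <- function(space = state_space(),
                                 edges = default_edges()) {
  stopifnot(inherits(space, "state_space"))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L) stop("'edges' must have two columns (from, to)")
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!all(c(edges$from, edges$to) %in% space$states))
    stop("edge labels must be states of the space")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  if (any(edges$from %in% space$absorbing))
    stop("no edge may leave an absorbing state")
  if (anyDuplicated(edges[c("from", "to")])) stop("duplicate edges")
  ts <- structure(
    list(space = space,
         edges = data.frame(trans = seq_len(nrow(edges)), edges,
                            stringsAsFactors = FALSE)),
    class = "transition_structure")
  if (has_cycle(ts)) stop("transition graph must be acyclic (progressive model)")
  ts
}

#' @rdname transition_structure
#' @export
default_edges <- function() {
  rbind(
    c("Diagnosis",  "Thrombosis"),
    c("Diagnosis",  "OvertMF"),
    c("Diagnosis",  "BlastPhase"),
    c("Diagnosis",  "Death"),
    c("Thrombosis", "OvertMF"),
    c("Thrombosis", "BlastPhase"),
    c("Thrombosis", "Death"),
    c("OvertMF",    "BlastPhase"),
    c("OvertMF",    "Death"),
    c("BlastPhase", "Death"))
}

# depth-first cycle check on the edge list
has_cycle <- function(ts) {
  adj <- split(ts$edges$to, factor(ts$edges$from, levels = ts$space$states))
  colour <- stats::setNames(rep(0L, length(ts$space$states)), ts$space$states)
  visit <- function(v) {
    colour[v] <<- 1L
    for (w in adj[[v]]) {
      if (colour[w] == 1L) return(TRUE)
      if (colour[w] == 0L && visit(w)) return(TRUE)
    }
    colour[v] <<- 2L
    FALSE
  }
  for (v in ts$space$states) if (colour[v] == 0L && visit(v)) return(TRUE)
  FALSE
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure:", length(x$space$states), "states,",
      nrow(x$edges), "transitions\n")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

# edges leaving a state, as rows of ts$edges
exit_edges <- function(ts, from) ts$edges[ts$edges$from == from, , drop = FALSE]

# number of states
n_states <- function(ts) length(ts$space$states)

# match a state label to its index in the space
state_index <- function(ts, label) match(label, ts$space$states)
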