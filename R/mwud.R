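#' Initialise a mass-weighted urn allocation state
#'
#' The mass-weighted urn design (MWUD) keeps a per-arm "mass" `m_k` started
#' at `alpha_urn * target_k`. Each assignment draws arm `k` with probability
#' proportional to `max(m_k, 0)` over active arms, then replenishes:
#' `m_k <- m_k - 1 + target_k` for the winner and `m_j <- m_j + target_j`
#' for every other arm (total mass is conserved). The realised allocation
#' tracks the targets with imbalance bounded by roughly `alpha_urn`, while
#' remaining random draw by draw. Parents are assigned once: repeated calls
#' for the same `parent_id` return the logged arm with no urn update, which
#' gives every sibling (and every later occasion) the same assignment.
#'
#' The state is an environment (class `mwud_state`); [assign_arm()] and
#' [retarget()] update it in place.
#'
#' @param targets Named nonnegative vector of target allocation
#'   probabilities, summing to 1 (default [initial_targets()]: 1/5 control,
#'   1/15 each SMS arm).
#' @param alpha_urn Total urn mass; larger values allow more randomness and
#'   a looser imbalance bound. Default 4.
#' @return An object of class `mwud_state` with fields `targets`, `masses`,
#'   `alpha`, `n_assigned`, `active`, and assignment log.
#' @export
#' @examples
#' st <- init_allocation()
#' assign_arm(st, "P1")
#' allocation_probs(st)
init_allocation <- function(targets = initial_targets(), alpha_urn = 4) {
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop("targets must be named by arm", call. = FALSE)
  if (any(targets < 0) || abs(sum(targets) - 1) > 1e-9)
    stop("targets must be nonnegative and sum to 1", call. = FALSE)
  stopifnot(alpha_urn > 0)
  st <- new.env(parent = emptyenv())
  st$targets <- targets
  st$alpha <- alpha_urn
  st$masses <- alpha_urn * targets
  st$n_assigned <- stats::setNames(integer(length(targets)), names(targets))
  st$active <- stats::setNames(rep(TRUE, length(targets)), names(targets))
  st$log <- new.env(parent = emptyenv(), size = 4096L)
  class(st) <- "mwud_state"
  st
}

#' Current draw probabilities of the urn
#'
#' @param state An `mwud_state`.
#' @return Named vector proportional to `max(mass, 0)` over active arms
#'   (zero for inactive arms), summing to 1.
#' @export
allocation_probs <- function(state) {
  w <- pmax(state$masses, 0) * state$active
  if (sum(w) <= 0)
    stop("all urn masses are non-positive: invariant violation",
         call. = FALSE)
  w / sum(w)
}

#' Assign a parent to an arm
#'
#' Draws from the urn (see [init_allocation()]) unless the parent was
#' assigned before, in which case the logged arm is returned and the urn is
#' untouched.
#'
#' @param state An `mwud_state`; updated in place.
#' @param parent_id Non-empty parent identifier.
#' @param force_arm Optional arm label: record this assignment (and update
#'   the urn as if it had been drawn) instead of drawing. Used for audit
#'   replay and testing of the urn arithmetic.
#' @return The assigned arm label (character scalar).
#' @export
assign_arm <- function(state, parent_id, force_arm = NULL) {
  stopifnot(inherits(state, "mwud_state"))
  if (length(parent_id) != 1L || is.na(parent_id) || !nzchar(parent_id))
    stop("parent_id must be a non-empty string", call. = FALSE)
  prev <- state$log[[parent_id]]
  if (!is.null(prev)) return(prev)
  arms <- names(state$targets)
  if (is.null(force_arm)) {
    p <- allocation_probs(state)
    k <- sample.int(length(arms), 1L, prob = p)
  } else {
    k <- match(force_arm, arms)
    if (is.na(k) || !state$active[k])
      stop("force_arm must be an active arm", call. = FALSE)
  }
  state$masses <- state$masses + state$targets
  state$masses[k] <- state$masses[k] - 1
  state$n_assigned[k] <- state$n_assigned[k] + 1L
  state$log[[parent_id]] <- arms[k]
  arms[k]
}

#' Assign many parents in sequence
#'
#' Equivalent to calling [assign_arm()] once per id (in order), including
#' the logged-assignment short-circuit for repeated parents.
#'
#' @param state An `mwud_state`; updated in place.
#' @param parent_ids Character vector of parent identifiers.
#' @return Character vector of arm labels, one per parent.
#' @export
assign_arms <- function(state, parent_ids) {
  stopifnot(inherits(state, "mwud_state"))
  n <- length(parent_ids)
  arms <- names(state$targets)
  masses <- unname(state$masses)
  targets <- unname(state$targets)
  counts <- unname(state$n_assigned)
  act <- which(state$active)
  out <- character(n)
  log <- state$log
  for (i in seq_len(n)) {
    id <- parent_ids[i]
    if (is.na(id) || !nzchar(id))
      stop("parent_id must be a non-empty string", call. = FALSE)
    prev <- log[[id]]
    if (!is.null(prev)) { out[i] <- prev; next }
    w <- pmax.int(masses[act], 0)
    if (sum(w) <= 0)
      stop("all urn masses are non-positive: invariant violation",
           call. = FALSE)
    k <- act[sample.int(length(act), 1L, prob = w)]
    masses <- masses + targets
    masses[k] <- masses[k] - 1
    counts[k] <- counts[k] + 1L
    out[i] <- arms[k]
    log[[id]] <- arms[k]
  }
  state$masses <- stats::setNames(masses, arms)
  state$n_assigned <- stats::setNames(counts, arms)
  out
}

#' Retarget the urn after an interim analysis
#'
#' Replaces the target allocation probabilities and re-initialises the urn
#' masses to `alpha_urn * target`. Assignments already logged and per-arm
#' counts are preserved. Arms absent from `new_targets` (or given target 0
#' via `deactivate`) are deactivated permanently: a deactivated arm can
#' never be reactivated or drawn again.
#'
#' @param state An `mwud_state`; updated in place.
#' @param new_targets Named vector over currently active arms, summing to 1.
#' @param deactivate Character vector of arm labels to deactivate (their
#'   target becomes 0).
#' @return The state, invisibly.
#' @export
retarget <- function(state, new_targets, deactivate = NULL) {
  stopifnot(inherits(state, "mwud_state"))
  arms <- names(state$targets)
  if (!is.null(deactivate)) {
    k <- match(deactivate, arms)
    if (anyNA(k)) stop("unknown arm in deactivate", call. = FALSE)
    state$active[k] <- FALSE
  }
  miss <- setdiff(names(new_targets), arms)
  if (length(miss))
    stop("unknown arm in new_targets: ", paste(miss, collapse = ", "),
         call. = FALSE)
  inactive_pos <- which(new_targets[arms[!state$active]] > 0)
  if (length(inactive_pos))
    stop("cannot assign positive target to a deactivated arm", call. = FALSE)
  full <- stats::setNames(numeric(length(arms)), arms)
  full[names(new_targets)] <- new_targets
  full[!state$active] <- 0
  if (any(full < 0) || abs(sum(full) - 1) > 1e-9)
    stop("new targets must be nonnegative and sum to 1 over active arms",
         call. = FALSE)
  state$targets <- full
  state$masses <- state$alpha * full
  invisible(state)
}

#' Serialise / restore an allocation state
#'
#' `alloc_state_to_list()` converts the urn to a plain list (suitable for
#' `jsonlite::write_json()`); `alloc_state_from_list()` rebuilds it, so a
#' trial can checkpoint and restart its randomisation.
#'
#' @param state An `mwud_state`; `x` a list produced by
#'   `alloc_state_to_list()` (or parsed back from JSON).
#' @return A list, or a restored `mwud_state`.
#' @export
alloc_state_to_list <- function(state) {
  log <- as.list(state$log)
  list(targets = as.list(state$targets), alpha = state$alpha,
       masses = as.list(state$masses), n_assigned = as.list(state$n_assigned),
       active = as.list(state$active), assignments = log)
}

#' @rdname alloc_state_to_list
#' @export
alloc_state_from_list <- function(x) {
  st <- init_allocation(unlist(x$targets), x$alpha)
  st$masses <- unlist(x$masses)
  st$n_assigned <- stats::setNames(as.integer(unlist(x$n_assigned)),
                                   names(x$n_assigned))
  st$active <- unlist(x$active)
  for (p in names(x$assignments)) st$log[[p]] <- x$assignments[[p]]
  st
}

#' @export
print.mwud_state <- function(x, ...) {
  cat(sprintf("Mass-weighted urn: %d arms (%d active), alpha = %g, %d assigned\n",
              length(x$targets), sum(x$active), x$alpha, sum(x$n_assigned)))
  df <- data.frame(target = round(x$targets, 4),
                   mass = round(x$masses, 3),
                   n = x$n_assigned, active = x$active)
  print(df, ...)
  invisible(x)
}
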