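# Synchronous discrete-event kernel: components with instantaneous boolean
# signals ("sum of Kronecker deltas"), directed zero-delay port connections,
# time-triggered component events, and fixpoint resolution of each event
# instant against pre-event state.

NEVER <- -Inf

#' Create an empty model graph
#'
#' A model graph holds component instances, directed port connections
#' (always output -> input), and the model's boundary ports. Boundary input
#' ports act as event sources driven by external traces; boundary output
#' ports expose one internal output trace to the outside.
#'
#' @return An object of class `model_graph`.
#' @seealso [add_component()], [connect()], [simulate_model()]
#' @export
model_graph <- function() {
  structure(
    list(
      components = list(),
      connections = data.frame(from = character(), to = character(),
                               stringsAsFactors = FALSE),
      boundary_inputs = character(),
      boundary_outputs = character()
    ),
    class = "model_graph"
  )
}

#' Define a simulation component
#'
#' Components are the behavioural unit of the kernel. A component has named
#' input and output ports, a discrete state (a named list), an event handler
#' and, optionally, a timeout function that schedules a time-triggered event.
#'
#' The handler is called once per event instant in which the component
#' receives input or its timeout expires. It always sees the *pre-event*
#' state (the value right before the instant); the state it returns is
#' committed only after the whole instant has resolved. If further inputs of
#' the component fire later within the same instant (zero-delay feedback),
#' the handler is re-evaluated against the same pre-event state with the
#' enlarged input set, and its previous pending result is discarded.
#' Handlers must be monotone: an output fired for some input set must also
#' fire for any superset.
#'
#' @param id Component identifier, unique within a model.
#' @param type Free-form type label (used for introspection and diagrams).
#' @param inputs,outputs Character vectors of port names (unique per
#'   component, across both directions).
#' @param state Named list of discrete state variables.
#' @param handler `function(state, t, fired_inputs, timeout_fired, ctx)`
#'   returning `list(state = <new state>, fire = <character vector of output
#'   port names>)`. `fired_inputs` is the character vector of this
#'   component's input ports that fired at the instant; `ctx` carries the
#'   [sim_config()] in effect.
#' @param timeout_fn `function(state)` returning the absolute time of the
#'   next self-scheduled event, or `Inf` when none is pending. `NULL` for
#'   components without time events.
#' @param params Named numeric vector of the component's scalar parameters
#'   (introspection only; the handler reads them from `state`).
#' @return An object of class `sim_component`.
#' @export
new_component <- function(id, type, inputs = character(), outputs = character(),
                          state = list(), handler, timeout_fn = NULL,
                          params = numeric()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.function(handler),
            is.null(timeout_fn) || is.function(timeout_fn))
  if (grepl(".", id, fixed = TRUE))
    stop("component id must not contain '.': ", id)
  if (anyDuplicated(c(inputs, outputs)))
    stop("port names must be unique within component ", id)
  structure(
    list(id = id, type = type, inputs = inputs, outputs = outputs,
         state = state, handler = handler, timeout_fn = timeout_fn,
         params = params),
    class = "sim_component"
  )
}

#' @export
print.sim_component <- function(x, ...) {
  cat(sprintf("<sim_component> %s (%s)\n", x$id, x$type))
  cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  if (length(x$params))
    cat("  params: ", paste(names(x$params), signif(x$params, 6),
                            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Add a component or boundary port to a model
#'
#' @param model A [model_graph()].
#' @param component A [new_component()] object.
#' @return The updated model.
#' @export
add_component <- function(model, component) {
  stopifnot(inherits(model, "model_graph"), inherits(component, "sim_component"))
  if (component$id %in% names(model$components))
    stop("duplicate component id: ", component$id)
  model$components[[component$id]] <- component
  model
}

#' @rdname add_component
#' @param name Boundary port name (must not contain `.`).
#' @export
add_boundary_input <- function(model, name) {
  stopifnot(inherits(model, "model_graph"))
  if (grepl(".", name, fixed = TRUE)) stop("boundary port name must not contain '.'")
  if (name %in% c(model$boundary_inputs, model$boundary_outputs))
    stop("duplicate boundary port: ", name)
  model$boundary_inputs <- c(model$boundary_inputs, name)
  model
}

#' @rdname add_component
#' @export
add_boundary_output <- function(model, name) {
  stopifnot(inherits(model, "model_graph"))
  if (grepl(".", name, fixed = TRUE)) stop("boundary port name must not contain '.'")
  if (name %in% c(model$boundary_inputs, model$boundary_outputs))
    stop("duplicate boundary port: ", name)
  model$boundary_outputs <- c(model$boundary_outputs, name)
  model
}

# Classify a port reference. Internal ports are "component.port"; boundary
# ports are bare names. Returns list(kind, comp, port, id).
port_info <- function(model, ref) {
  if (grepl(".", ref, fixed = TRUE)) {
    parts <- strsplit(ref, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed port reference: ", ref)
    comp <- model$components[[parts[1L]]]
    if (is.null(comp)) stop("unknown component in port reference: ", ref)
    if (parts[2L] %in% comp$outputs) dir <- "output"
    else if (parts[2L] %in% comp$inputs) dir <- "input"
    else stop("unknown port: ", ref)
    list(kind = dir, comp = parts[1L], port = parts[2L], id = ref)
  } else if (ref %in% model$boundary_inputs) {
    list(kind = "boundary_input", comp = NA_character_, port = ref, id = ref)
  } else if (ref %in% model$boundary_outputs) {
    list(kind = "boundary_output", comp = NA_character_, port = ref, id = ref)
  } else {
    stop("unknown port: ", ref)
  }
}

#' Connect two ports
#'
#' Adds a directed, zero-delay connection. Causality is enforced: the source
#' must be a component output port or a model boundary input; the target must
#' be a component input port or a model boundary output. Each input port
#' accepts at most one incoming connection (fan-in is expressed with explicit
#' logic-gate components); an output may fan out to any number of inputs.
#' Connecting an already-connected pair is an error.
#'
#' @param model A [model_graph()].
#' @param source,target Port references: `"component.port"` for component
#'   ports, a bare name for boundary ports.
#' @return The updated model.
#' @examples
#' m <- model_graph()
#' m <- add_boundary_input(m, "inp")
#' m <- add_boundary_output(m, "outp")
#' m <- add_component(m, refractory_gate("gate", d_refrac = 0.3))
#' m <- connect(m, "inp", "gate.inp")
#' m <- connect(m, "gate.outp", "outp")
#' @export
connect <- function(model, source, target) {
  stopifnot(inherits(model, "model_graph"))
  src <- port_info(model, source)
  dst <- port_info(model, target)
  if (!src$kind %in% c("output", "boundary_input"))
    stop("causality violation: source of a connection must be an output ",
         "port or a boundary input, got ", source)
  if (!dst$kind %in% c("input", "boundary_output"))
    stop("causality violation: target of a connection must be an input ",
         "port or a boundary output, got ", target)
  dup <- model$connections$from == src$id & model$connections$to == dst$id
  if (any(dup)) stop("duplicate connection: ", source, " -> ", target)
  if (dst$id %in% model$connections$to)
    stop("input port ", target, " already has an incoming connection; ",
         "route fan-in through an explicit logic gate")
  model$connections <- rbind(
    model$connections,
    data.frame(from = src$id, to = dst$id, stringsAsFactors = FALSE)
  )
  model
}

#' Simulation configuration
#'
#' @param t_start,t_stop Simulation window, seconds; `t_start < t_stop`
#'   (equal endpoints are allowed for degenerate single-instant runs).
#' @param time_tolerance Events closer than this are merged into one instant
#'   (seconds, > 0).
#' @param overlap_policy What a [conduction_delay()] does when an input
#'   arrives while a signal is already on hold: `"warn_drop"` (default; the
#'   input is ignored with a warning), `"silent_drop"`, or `"error"`.
#' @param seed Integer seed recorded in provenance; the kernel itself is
#'   deterministic and draws no random numbers.
#' @param max_event_iterations Fixpoint iteration cap per instant; exceeding
#'   it signals an algebraic event loop.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(t_start = 0, t_stop = 60, time_tolerance = 1e-9,
                       overlap_policy = c("warn_drop", "silent_drop", "error"),
                       seed = 1L, max_event_iterations = 100L) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(is.finite(t_start), is.finite(t_stop), t_start <= t_stop,
            time_tolerance > 0, max_event_iterations >= 1L)
  structure(
    list(t_start = t_start, t_stop = t_stop, time_tolerance = time_tolerance,
         overlap_policy = overlap_policy, seed = as.integer(seed),
         max_event_iterations = as.integer(max_event_iterations)),
    class = "sim_config"
  )
}

# per component: map input port name -> source port id (NA if unconnected)
input_source_map <- function(model) {
  lapply(model$components, function(comp) {
    if (!length(comp$inputs)) return(character())
    vapply(comp$inputs, function(p)
      incoming_source(model, paste0(comp$id, ".", p)), character(1))
  })
}

# source port feeding an input port, or NA if unconnected
incoming_source <- function(model, input_id) {
  hit <- model$connections$from[model$connections$to == input_id]
  if (length(hit)) hit[1L] else NA_character_
}

#' Earliest pending time-triggered event
#'
#' Scans all component timeout functions and returns the earliest pending
#' expiry, or `NULL` when every component is idle.
#'
#' @param model A [model_graph()] with initialised component states.
#' @return `NULL`, or `list(time = <numeric>, component = <id>)`.
#' @export
next_timeout <- function(model) {
  best_t <- Inf
  best_id <- NA_character_
  for (comp in model$components) {
    if (is.null(comp$timeout_fn)) next
    tt <- comp$timeout_fn(comp$state)
    if (is.finite(tt) && tt < best_t) {
      best_t <- tt
      best_id <- comp$id
    }
  }
  if (is.na(best_id)) NULL else list(time = best_t, component = best_id)
}

# Core instant resolution. states: named list of component states.
# seed_ports: source-port ids (boundary inputs or "comp.port" outputs) that
# fire at t before any propagation. timeout_comps: ids whose timeout expired
# at t. Returns list(fired = character ids, states = committed states).
resolve_instant_core <- function(model, t, seed_ports, timeout_comps, states,
                                 config, src_of = NULL) {
  fired <- unique(seed_ports)
  pending <- list()
  comp_ids <- names(model$components)
  # cache: per component, map input port name -> source port id
  if (is.null(src_of)) src_of <- input_source_map(model)
  last_key <- setNames(rep(NA_character_, length(comp_ids)), comp_ids)
  ctx <- list(config = config)
  for (iter in seq_len(config$max_event_iterations)) {
    changed <- FALSE
    for (cid in comp_ids) {
      comp <- model$components[[cid]]
      srcs <- src_of[[cid]]
      fired_inputs <- comp$inputs[!is.na(srcs) & srcs %in% fired]
      to_fired <- cid %in% timeout_comps
      if (!length(fired_inputs) && !to_fired) next
      key <- paste(sort(fired_inputs), collapse = ",")
      if (!is.na(last_key[[cid]]) && identical(last_key[[cid]], key)) next
      last_key[[cid]] <- key
      res <- comp$handler(states[[cid]], t, fired_inputs, to_fired, ctx)
      pending[[cid]] <- res$state
      for (out in res$fire) {
        pid <- paste0(cid, ".", out)
        if (!pid %in% fired) {
          fired <- c(fired, pid)
          changed <- TRUE
        }
      }
    }
    if (!changed) {
      for (cid in names(pending)) states[[cid]] <- pending[[cid]]
      return(list(fired = fired, states = states))
    }
  }
  stop("event iteration did not converge within ", config$max_event_iterations,
       " iterations at t = ", t, " (algebraic event loop?)")
}

#' Resolve a single event instant
#'
#' Propagates a set of initially firing source ports through the model at one
#' instant `t`, evaluating every event handler against pre-event state,
#' firing each output at most once, and committing state updates once the
#' zero-delay fixpoint is reached.
#'
#' @param model A [model_graph()].
#' @param t The event instant (seconds).
#' @param initial_emissions Character vector of source ports firing at `t`
#'   (boundary inputs and/or component outputs whose timeout expired).
#' @param config A [sim_config()].
#' @param timeout_components Component ids whose time event expires at `t`.
#' @return `list(fired = <all source ports that fired>, model = <model with
#'   committed post-instant states>)`.
#' @export
resolve_instant <- function(model, t, initial_emissions = character(),
                            config = sim_config(), timeout_components = character()) {
  states <- lapply(model$components, `[[`, "state")
  res <- resolve_instant_core(model, t, initial_emissions, timeout_components,
                              states, config)
  for (cid in names(res$states)) model$components[[cid]]$state <- res$states[[cid]]
  list(fired = res$fired, model = model)
}

#' Run an event-driven simulation
#'
#' Chronologically processes external boundary events and component time
#' events over `[t_start, t_stop]`, merging events closer than
#' `time_tolerance` into one instant and resolving each instant with
#' synchronous zero-delay propagation. The function is deterministic:
#' identical `(model, config, external)` yield identical results.
#'
#' @param model A [model_graph()].
#' @param config A [sim_config()].
#' @param external Named list mapping boundary input names to numeric event
#'   traces (strictly increasing times within the window).
#' @return An object of class `sim_result`: a list with `traces` (named list
#'   of event-time vectors for every boundary input and component output
#'   port), the post-simulation `model`, the `config`, and `external`.
#'   Use [port_trace()] to read any port, including input ports and boundary
#'   outputs (which mirror their source by zero-delay propagation).
#' @export
simulate_model <- function(model, config = sim_config(), external = list()) {
  stopifnot(inherits(model, "model_graph"), inherits(config, "sim_config"))
  tol <- config$time_tolerance
  unknown <- setdiff(names(external), model$boundary_inputs)
  if (length(unknown))
    stop("external traces for unknown boundary inputs: ",
         paste(unknown, collapse = ", "))
  for (nm in names(external)) {
    tr <- external[[nm]]
    if (length(tr)) {
      if (is.unsorted(tr, strictly = TRUE))
        stop("external trace for '", nm, "' must be strictly increasing")
      if (tr[1L] < config$t_start - tol || tr[length(tr)] > config$t_stop + tol)
        stop("external trace for '", nm, "' leaves the simulation window")
    }
  }

  states <- lapply(model$components, `[[`, "state")
  out_ports <- unlist(lapply(model$components, function(comp)
    if (length(comp$outputs)) paste0(comp$id, ".", comp$outputs) else character()),
    use.names = FALSE)
  traces <- setNames(vector("list", length(out_ports) + length(model$boundary_inputs)),
                     c(model$boundary_inputs, out_ports))
  traces[] <- list(numeric())

  ext_idx <- setNames(rep(1L, length(model$boundary_inputs)), model$boundary_inputs)
  timeout_of <- function(cid) {
    fn <- model$components[[cid]]$timeout_fn
    if (is.null(fn)) Inf else fn(states[[cid]])
  }
  comp_ids <- names(model$components)
  src_of <- input_source_map(model)
  t_prev <- -Inf

  repeat {
    t_ext <- Inf
    for (nm in model$boundary_inputs) {
      tr <- external[[nm]]
      i <- ext_idx[[nm]]
      if (!is.null(tr) && i <= length(tr) && tr[i] < t_ext) t_ext <- tr[i]
    }
    t_to <- Inf
    for (cid in comp_ids) {
      tt <- timeout_of(cid)
      if (tt < t_to) t_to <- tt
    }
    t <- min(t_ext, t_to)
    if (!is.finite(t) || t > config$t_stop + tol) break
    if (t < t_prev - tol)
      stop("internal error: event scheduled in the past at t = ", t)

    seed_ports <- character()
    for (nm in model$boundary_inputs) {
      tr <- external[[nm]]
      i <- ext_idx[[nm]]
      if (!is.null(tr) && i <= length(tr) && tr[i] <= t + tol) {
        seed_ports <- c(seed_ports, nm)
        ext_idx[[nm]] <- i + 1L
      }
    }
    timeout_comps <- comp_ids[vapply(comp_ids, function(cid)
      timeout_of(cid) <= t + tol, logical(1))]

    res <- resolve_instant_core(model, t, seed_ports, timeout_comps, states,
                                config, src_of)
    states <- res$states
    for (pid in res$fired) traces[[pid]] <- c(traces[[pid]], t)
    t_prev <- t
  }

  for (cid in comp_ids) model$components[[cid]]$state <- states[[cid]]
  structure(
    list(traces = traces, model = model, config = config, external = external),
    class = "sim_result"
  )
}

#' Read the event trace of any port
#'
#' Output ports and boundary inputs are read from the recorded traces; input
#' ports and boundary outputs mirror the trace of their connected source
#' (zero-delay propagation makes them identical by construction).
#'
#' @param result A `sim_result` from [simulate_model()].
#' @param port Port reference (`"component.port"` or a boundary name).
#' @return Numeric vector of event times.
#' @export
port_trace <- function(result, port) {
  stopifnot(inherits(result, "sim_result"))
  model <- result$model
  if (port %in% names(result$traces)) return(result$traces[[port]])
  info <- port_info(model, port)
  if (info$kind %in% c("input", "boundary_output")) {
    src <- incoming_source(model, info$id)
    if (is.na(src)) return(numeric())
    return(result$traces[[src]])
  }
  stop("no trace recorded for port: ", port)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> window [%g, %g] s\n", x$config$t_start, x$config$t_stop))
  n <- vapply(x$traces, length, integer(1))
  for (nm in names(n)) cat(sprintf("  %-28s %d events\n", nm, n[[nm]]))
  invisible(x)
}
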