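#' Rhythm classification
#'
#' The engine branches on the rhythm identified at the monitor:
#' VF and pulseless VT are shockable, asystole and PEA nonshockable, and
#' an organized rhythm with a pulse exits to the post-resuscitation
#' pathway.
#'
#' @param rhythm One of `"ASYSTOLE"`, `"PEA"`, `"VF"`, `"PVT"`,
#'   `"ORGANIZED_WITH_PULSE"`.
#' @return `"nonshockable"`, `"shockable"` or `"rosc"`.
#' @export
rhythm_class <- function(rhythm) {
  if (!is_scalar_string(rhythm) || !rhythm %in% rhythm_values())
    stop("unknown rhythm: ", paste(rhythm, collapse = ", "), call. = FALSE)
  switch(rhythm,
         ASYSTOLE = , PEA = "nonshockable",
         VF = , PVT = "shockable",
         ORGANIZED_WITH_PULSE = "rosc")
}

rhythm_values <- function() {
  c("ASYSTOLE", "PEA", "VF", "PVT", "ORGANIZED_WITH_PULSE")
}

log_event_types <- function() {
  c("CASE_START", "TAP", "RHYTHM_SELECTED", "TIMER_FIRED", "ALERT_RAISED",
    "OVERLAY_OPENED", "OVERLAY_CLOSED", "DOSE_COMPUTED", "SHOCK_ADVISED",
    "ROSC_DECLARED", "CASE_END")
}

#' Load and validate a guidance flow graph
#'
#' The flow graph is declarative data: a set of screens (nodes), each
#' holding either an ordered list of sequential action buttons or a
#' mutually exclusive set of alternative choice buttons, with edges to
#' successor screens. Validation enforces the structural invariants:
#' every edge target exists, every node is reachable from the start node,
#' the advance rule matches the button layout, and both the shockable and
#' nonshockable pathway tags are populated.
#'
#' @param path Path to a YAML flow-graph file; defaults to the bundled
#'   graph encoding the shared entry, rhythm choice, nonshockable and
#'   shockable pathways and post-resuscitation care.
#' @return A validated object of class `flow_graph`.
#' @examples
#' g <- load_flow_graph()
#' names(g$nodes)
#' @export
load_flow_graph <- function(path = resusim_extdata("flow_graph.yaml")) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("flow graph parse error: ", conditionMessage(e), call. = FALSE))
  if (is.null(raw$nodes) || is.null(raw$start_node))
    stop("flow graph schema violation: 'nodes' and 'start_node' required",
         call. = FALSE)
  nodes <- list()
  for (nd in raw$nodes) {
    if (!is_scalar_string(nd$id))
      stop("flow graph schema violation: node without id", call. = FALSE)
    nodes[[nd$id]] <- validate_flow_node(nd)
  }
  g <- structure(list(nodes = nodes,
                      start_node = raw$start_node,
                      pathway_tags = raw$pathway_tags %||% list()),
                 class = "flow_graph")
  validate_flow_graph(g)
}

validate_flow_node <- function(nd) {
  id <- nd$id
  btns <- nd$buttons %||% list()
  for (b in btns) {
    if (!is_scalar_string(b$id) || !is_scalar_string(b$layout))
      stop("schema violation in node '", id, "': button needs id and layout",
           call. = FALSE)
    if (!b$layout %in% c("SEQUENTIAL", "ALTERNATIVE"))
      stop("schema violation in node '", id, "': bad layout '", b$layout, "'",
           call. = FALSE)
    if (!(b$kind %||% "ACTION") %in% c("ACTION", "CHOICE"))
      stop("schema violation in node '", id, "': bad kind", call. = FALSE)
  }
  layouts <- vapply(btns, function(b) b$layout, "")
  rule <- nd$advance_rule %||% "ALL_SEQUENTIAL_TAPPED"
  if (!rule %in% c("ALL_SEQUENTIAL_TAPPED", "ONE_CHOICE_SELECTED"))
    stop("schema violation in node '", id, "': bad advance_rule", call. = FALSE)
  if (rule == "ALL_SEQUENTIAL_TAPPED" && any(layouts == "ALTERNATIVE"))
    stop("schema violation in node '", id,
         "': sequential advance rule with alternative buttons", call. = FALSE)
  if (rule == "ONE_CHOICE_SELECTED" && sum(layouts == "ALTERNATIVE") < 2)
    stop("schema violation in node '", id,
         "': choice rule requires >= 2 alternative buttons", call. = FALSE)
  list(id = id,
       buttons = btns,
       advance_rule = rule,
       on_advance = nd$on_advance,
       rhythm_choice = isTRUE(nd$rhythm_choice))
}

validate_flow_graph <- function(g) {
  ids <- names(g$nodes)
  if (!g$start_node %in% ids)
    stop("flow graph validation error: start node '", g$start_node,
         "' not defined", call. = FALSE)
  # every edge target must exist
  for (nd in g$nodes) {
    for (target in edge_targets(nd)) {
      if (!target %in% ids)
        stop("flow graph validation error: node '", nd$id,
             "' references missing node '", target, "'", call. = FALSE)
    }
  }
  unreachable <- setdiff(ids, reachable_nodes(g))
  if (length(unreachable))
    stop("flow graph validation error: unreachable node(s): ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  tags <- unlist(g$pathway_tags, use.names = FALSE)
  # a tagged graph must cover both rhythm pathways; untagged (toy) graphs
  # are allowed
  if (length(tags) &&
      (!"shockable" %in% tags || !"nonshockable" %in% tags))
    stop("flow graph validation error: both shockable and nonshockable ",
         "pathway tags must be populated", call. = FALSE)
  g
}

edge_targets <- function(node) {
  oa <- node$on_advance
  if (is.null(oa)) character(0)
  else if (is.list(oa)) unlist(oa, use.names = FALSE)
  else as.character(oa)
}

#' Nodes reachable from the start node
#'
#' @param graph A `flow_graph`.
#' @return Character vector of reachable node ids (breadth-first order).
#' @export
reachable_nodes <- function(graph) {
  seen <- character(0)
  frontier <- graph$start_node
  while (length(frontier)) {
    id <- frontier[[1]]
    frontier <- frontier[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    frontier <- c(frontier, setdiff(edge_targets(graph$nodes[[id]]), seen))
  }
  seen
}

#' @export
print.flow_graph <- function(x, ...) {
  cat("<flow_graph> ", length(x$nodes), " nodes, start = '", x$start_node,
      "'\n", sep = "")
  for (nd in x$nodes) {
    tag <- x$pathway_tags[[nd$id]] %||% "?"
    cat("  ", format(nd$id, width = 20), " [", tag, "] ",
        length(nd$buttons), " buttons -> ",
        paste(edge_targets(nd), collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}
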