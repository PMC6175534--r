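# Protein-group membership lists and universe partitioning.

.GROUP_ROLES <- c("mito", "ribosome", "er_perox", "autophagy_substrate",
                  "proteasome_substrate", "kferq_positive",
                  "endocytic_substrate", "endosomal_machinery",
                  "ev_compiled", "ev_top100", "custom")

.normalize_ids <- function(x) toupper(trimws(as.character(x)))

#' Construct a protein group
#'
#' A named membership set with a role tag. Member ids are whitespace- and
#' case-normalized; duplicates are dropped with a warning.
#'
#' @param name Group name.
#' @param members Character vector of protein ids.
#' @param role One of the recognised role tags (substrate classes,
#'   machinery, EV lists) or `"custom"`.
#' @param provenance Free-text note on where the list came from.
#' @return An object of class `protein_group`.
#' @export
protein_group <- function(name, members, role = "custom", provenance = "") {
  role <- match.arg(role, .GROUP_ROLES)
  members <- .normalize_ids(members)
  members <- members[nzchar(members)]
  if (!length(members)) stop("group '", name, "' has no members")
  if (anyDuplicated(members)) {
    warning("group '", name, "': ", sum(duplicated(members)),
            " duplicate id(s) collapsed")
    members <- unique(members)
  }
  structure(list(name = name, role = role, members = members,
                 provenance = provenance), class = "protein_group")
}

#' @export
print.protein_group <- function(x, ...) {
  cat("Protein group '", x$name, "' (role: ", x$role, "): ",
      length(x$members), " members\n", sep = "")
  invisible(x)
}

#' Load protein-group membership lists from TSV files
#'
#' Each file must have a `protein_id` column and may have a `group` column
#' splitting it into several groups; otherwise the file (or list element)
#' name is the group name. Roles are taken from `roles` (named by group) or
#' inferred from group names matching a role tag. Two structural rules are
#' enforced: endocytic substrates and endosomal machinery must be disjoint
#' (a shared id is a hard error naming the offenders), and when the three
#' organellar substrate groups (`mito`, `ribosome`, `er_perox`) are all
#' present a composite `autophagy_substrate` union group is added.
#'
#' @param paths Character vector of TSV paths (names become group names when
#'   no `group` column is present).
#' @param roles Optional named character vector mapping group name to role.
#' @return Named list of [protein_group()] objects.
#' @export
load_groups <- function(paths, roles = NULL) {
  groups <- list()
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!nrow(x)) stop("empty group file: ", path)
    if (is.null(x$protein_id))
      stop("group file ", path, " lacks a 'protein_id' column")
    default_name <- if (!is.null(names(paths)) && nzchar(names(paths)[i]))
      names(paths)[i] else sub("\\.[^.]*$", "", basename(path))
    by_group <- if (!is.null(x$group)) split(x$protein_id, x$group)
                else stats::setNames(list(x$protein_id), default_name)
    for (g in names(by_group)) {
      role <- if (!is.null(roles) && g %in% names(roles)) roles[[g]]
              else if (g %in% .GROUP_ROLES) g else "custom"
      groups[[g]] <- protein_group(g, by_group[[g]], role,
                                   provenance = path)
    }
  }
  .validate_groups(groups)
}

# cross-group invariants + composite autophagy-substrate group
.validate_groups <- function(groups) {
  roles <- vapply(groups, `[[`, "", "role")
  endo <- which(roles == "endocytic_substrate")
  mach <- which(roles == "endosomal_machinery")
  if (length(endo) && length(mach)) {
    overlap <- intersect(
      unique(unlist(lapply(groups[endo], `[[`, "members"))),
      unique(unlist(lapply(groups[mach], `[[`, "members"))))
    if (length(overlap))
      stop("endocytic_substrate and endosomal_machinery overlap: ",
           paste(utils::head(overlap, 10), collapse = ", "))
  }
  org <- c("mito", "ribosome", "er_perox")
  if (all(org %in% roles) && !"autophagy_substrate" %in% roles) {
    members <- unique(unlist(lapply(groups[roles %in% org], `[[`, "members")))
    groups[["autophagy_substrate"]] <-
      protein_group("autophagy_substrate", members, "autophagy_substrate",
                    provenance = "union of mito, ribosome, er_perox")
  }
  groups
}

#' Build groups from a synthetic ground truth
#'
#' Turns the class labels of a simulated proteome into [protein_group()]s
#' (one per class whose label matches a role tag, plus the
#' autophagy-substrate union when the three organellar classes exist).
#'
#' @param truth A `ground_truth`.
#' @return Named list of `protein_group` objects.
#' @export
groups_from_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  by_class <- split(truth$proteins$protein_id, truth$proteins$class_label)
  groups <- list()
  for (g in names(by_class)) {
    role <- if (g %in% .GROUP_ROLES) g else if (g == "ev") "ev_compiled"
            else "custom"
    groups[[g]] <- protein_group(g, by_class[[g]], role,
                                 provenance = "simulated class label")
  }
  .validate_groups(groups)
}

#' Partition a dataset universe against a protein group
#'
#' @param universe Character vector of protein ids present in a dataset.
#' @param group A [protein_group()] (or plain character vector of members).
#' @return List with `in_group` (members found in the universe),
#'   `out_group` (the rest of the universe), and their sizes `n_in`,
#'   `n_out`.
#' @export
partition_universe <- function(universe, group) {
  if (!length(universe)) stop("dataset universe is empty")
  members <- if (inherits(group, "protein_group")) group$members
             else .normalize_ids(group)
  universe <- unique(.normalize_ids(universe))
  in_g <- intersect(universe, members)
  out_g <- setdiff(universe, members)
  list(in_group = in_g, out_group = out_g,
       n_in = length(in_g), n_out = length(out_g))
}

#' Summarise group sizes and overlaps as JSON-ready structure
#'
#' @param groups Named list of `protein_group` objects.
#' @param universe Optional dataset universe for present-in-data counts.
#' @return A list (group -> size, role, n_in_universe) suitable for
#'   [jsonlite::write_json()].
#' @export
group_summary <- function(groups, universe = NULL) {
  lapply(groups, function(g) {
    out <- list(role = g$role, size = length(g$members))
    if (!is.null(universe))
      out$n_in_universe <- partition_universe(universe, g)$n_in
    out
  })
}
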