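#' Load the arptraj configuration
#'
#' Reads the structured YAML configuration holding dialect chain maps,
#' subdomain residue ranges, anchors, clamp-bead definitions and numerical
#' parameters. With `path = NULL` the configuration shipped with the
#' package is used.
#'
#' @param path path to a YAML config file, or `NULL` for the shipped one.
#' @return a nested list (see the shipped `arptraj-config.yaml` for the
#'   schema).
#' @export
arptraj_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "arptraj-config.yaml", package = "arptraj",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  for (k in c("dialects", "sasa", "contacts", "geometry", "steer"))
    if (is.null(cfg[[k]])) stop("config is missing section '", k, "'")
  cfg
}

#' Resolve the subunit registry for a structure
#'
#' Maps the chain identifiers of a structure dialect to canonical subunit
#' names (Arp2, Arp3, ARPC1-5, mother MA0-MA9, daughter DA1-DA4) and
#' attaches subdomain residue ranges, named residue anchors, clamp-bead
#' definitions and the list of mother-filament subunits excluded from
#' trajectory BSA.
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param dialect `"synthetic"`, `"7TPT"`, `"4JD2"`, or a custom list with
#'   the same fields as a config dialect entry (at minimum `chains`).
#' @param require canonical subunit names that must resolve to chains
#'   present in the structure; defaults to Arp2 and Arp3.
#' @param config configuration list from [arptraj_config()].
#' @return a `subunit_registry` object.
#' @export
resolve_registry <- function(x, dialect = "synthetic",
                             require = c("Arp2", "Arp3"),
                             config = arptraj_config()) {
  top <- topology_of(x)
  if (is.character(dialect)) {
    dl <- config$dialects[[dialect]]
    if (is.null(dl))
      stop("unknown dialect '", dialect, "'; configured dialects: ",
           paste(names(config$dialects), collapse = ", "))
    dname <- dialect
  } else if (is.list(dialect)) {
    dl <- dialect
    dname <- "custom"
    if (is.null(dl$chains)) stop("custom dialect must supply a 'chains' map")
    # fall back to synthetic-dialect metadata for unspecified fields
    base <- config$dialects$synthetic
    for (k in c("subdomains", "anchors", "clamp_beads", "mf_excluded"))
      if (is.null(dl[[k]])) dl[[k]] <- base[[k]]
  } else stop("dialect must be a name or a custom list")

  chains_present <- unique(top$atoms$chain)
  map <- unlist(dl$chains)
  found <- map[map %in% chains_present]
  missing_required <- setdiff(require, names(found))
  if (length(missing_required))
    stop("required subunits not found in structure: ",
         paste(missing_required, collapse = ", "))
  reg <- structure(list(
    dialect = dname,
    chains = found,
    subdomains = dl$subdomains,
    anchors = dl$anchors,
    clamp_beads = dl$clamp_beads,
    mf_excluded = as.character(dl$mf_excluded %||% character()),
    unmapped_chains = setdiff(chains_present, map)
  ), class = "subunit_registry")
  validate_registry(reg)
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_registry <- function(reg) {
  for (su in names(reg$subdomains)) {
    sd <- reg$subdomains[[su]]
    if (!all(c("sd1", "sd2", "sd3", "sd4") %in% names(sd)))
      stop("subunit '", su, "' must define subdomains sd1..sd4")
    res <- lapply(sd, function(rr) unlist(lapply(rr, function(ab)
      seq(ab[[1]], ab[[2]]))))
    all_res <- unlist(res)
    if (anyDuplicated(all_res))
      stop("subdomain ranges of '", su, "' overlap")
  }
  invisible(reg)
}

#' Subunits present in a registry
#' @param reg a `subunit_registry`.
#' @export
subunits <- function(reg) names(reg$chains)

#' @export
print.subunit_registry <- function(x, ...) {
  cat("subunit_registry (dialect ", x$dialect, "): ",
      length(x$chains), " subunits mapped\n  ", sep = "")
  cat(paste0(names(x$chains), "=", x$chains), fill = 70)
  if (length(x$unmapped_chains))
    cat("  unmapped chains:", paste(x$unmapped_chains, collapse = " "), "\n")
  invisible(x)
}

# subdomain residue numbers for a canonical subunit; actin-like subunits
# (MA*/DA*) fall back to the "actin" entry.
subdomain_resnos <- function(reg, subunit, subdomain) {
  key <- if (subunit %in% names(reg$subdomains)) subunit else
    if (grepl("^(MA|DA)", subunit)) "actin" else subunit
  sd <- reg$subdomains[[key]]
  if (is.null(sd)) stop("no subdomain definition for subunit '", subunit, "'")
  rr <- sd[[paste0("sd", subdomain)]]
  if (is.null(rr)) stop("no subdomain ", subdomain, " for subunit '", subunit, "'")
  unlist(lapply(rr, function(ab) seq(ab[[1]], ab[[2]])))
}

#' Select atoms by subunit, subdomain, residue and atom name
#'
#' Deterministic atom selection against the registry's canonical naming. An
#' empty result is an error (it almost always indicates a wrong selection
#' expression), never an empty set.
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param registry a `subunit_registry`.
#' @param subunit canonical subunit name(s), e.g. `"Arp3"`; `NULL` for all.
#' @param subdomain subdomain indices 1-4 (requires a single subunit class).
#' @param resno residue numbers to keep, `NULL` for all.
#' @param elety atom names to keep (e.g. `"CA"`), `NULL` for all.
#' @param backbone if `TRUE`, keep protein backbone atoms N, CA, C, O only.
#' @return integer vector of atom indices into the topology.
#' @export
select_atoms <- function(x, registry, subunit = NULL, subdomain = NULL,
                         resno = NULL, elety = NULL, backbone = FALSE) {
  at <- topology_of(x)$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(subunit)) {
    miss <- setdiff(subunit, names(registry$chains))
    if (length(miss))
      stop("subunit(s) not in registry: ", paste(miss, collapse = ", "))
    keep <- keep & at$chain %in% registry$chains[subunit]
  }
  if (!is.null(subdomain)) {
    if (is.null(subunit) || length(subunit) != 1)
      stop("subdomain selection requires exactly one subunit")
    rn <- unlist(lapply(subdomain, function(s)
      subdomain_resnos(registry, subunit, s)))
    keep <- keep & at$resno %in% rn
  }
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(elety)) keep <- keep & trimws(at$elety) %in% elety
  if (backbone) keep <- keep & trimws(at$elety) %in% c("N", "CA", "C", "O")
  idx <- which(keep)
  if (length(idx) == 0)
    stop("empty selection: subunit=", deparse(subunit),
         " subdomain=", deparse(subdomain), " resno=", deparse(substr(paste(
           deparse(resno), collapse = ""), 1, 40)),
         " elety=", deparse(elety), " backbone=", backbone)
  idx
}

# resolve a named anchor to a single atom index
anchor_atom <- function(x, registry, anchor, elety = "CA") {
  a <- registry$anchors[[anchor]]
  if (is.null(a)) stop("unknown anchor '", anchor, "'; registry defines: ",
                       paste(names(registry$anchors), collapse = ", "))
  idx <- tryCatch(
    select_atoms(x, registry, subunit = a$subunit, resno = a$resno,
                 elety = elety),
    error = function(e) stop("anchor '", anchor, "' (", a$subunit, " residue ",
                             a$resno, " ", elety, ") not present: ",
                             conditionMessage(e), call. = FALSE))
  if (length(idx) != 1)
    stop("anchor '", anchor, "' resolves to ", length(idx),
         " atoms; expected exactly 1")
  idx
}
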