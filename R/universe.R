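# Reaction universe: the global catalogue of compounds and directed reactions
# indexed by EC number, plus per-organism network reconstruction from EC lists.

EC_PATTERN <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

#' Validate EC number syntax
#'
#' EC strings have four dot-separated fields; trailing fields may be `-`
#' (partial ECs, as emitted by most annotation pipelines).
#'
#' @param ec Character vector of candidate EC strings.
#' @return Logical vector, `TRUE` where the syntax is valid.
#' @export
is_valid_ec <- function(ec) {
  grepl(EC_PATTERN, ec)
}

new_reaction <- function(id, ec, substrates, products, from_reversible = FALSE,
                         parent = id) {
  list(id = id, ec = ec, substrates = unique(substrates),
       products = unique(products), from_reversible = from_reversible,
       parent = parent)
}

build_ec_index <- function(reactions) {
  ecs <- lapply(reactions, `[[`, "ec")
  ids <- rep(vapply(reactions, `[[`, "", "id"), lengths(ecs))
  split(ids, unlist(ecs))
}

#' Construct a reaction universe
#'
#' A universe couples a compound table with a set of directed reactions and an
#' EC index.  Reversible reactions must already be split into their two
#' directions (see [load_universe()]).
#'
#' @param compounds Data frame with columns `id`, `name`, `pathway_class`
#'   (the latter two optional; filled with `NA` when missing).
#' @param reactions List of reaction records as built by the loader: each a
#'   list with `id`, `ec` (character vector), `substrates`, `products`,
#'   `from_reversible`, `parent`.
#' @return An object of class `reaction_universe`.
#' @export
reaction_universe <- function(compounds, reactions) {
  if (is.character(compounds)) {
    compounds <- data.frame(id = compounds, name = compounds,
                            pathway_class = NA_character_,
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(compounds), "id" %in% names(compounds))
  if (!"name" %in% names(compounds)) compounds$name <- compounds$id
  if (!"pathway_class" %in% names(compounds)) {
    compounds$pathway_class <- NA_character_
  }
  if (anyDuplicated(compounds$id)) {
    stop("duplicate compound id(s): ",
         paste(unique(compounds$id[duplicated(compounds$id)]), collapse = ", "))
  }
  if (any(!nzchar(compounds$id))) stop("empty compound id")
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reactions) <- ids
  known <- compounds$id
  for (r in reactions) {
    if (length(r$substrates) == 0L || length(r$products) == 0L) {
      stop("reaction ", r$id, ": substrates and products must be non-empty")
    }
    miss <- setdiff(c(r$substrates, r$products), known)
    if (length(miss)) {
      stop("reaction ", r$id, " references unknown compound(s): ",
           paste(miss, collapse = ", "))
    }
    bad <- r$ec[!is_valid_ec(r$ec)]
    if (length(bad)) {
      stop("reaction ", r$id, " has malformed EC(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(compounds = compounds, reactions = reactions,
                 ec_index = build_ec_index(reactions)),
            class = "reaction_universe")
}

#' @export
print.reaction_universe <- function(x, ...) {
  cat("<reaction_universe> ", nrow(x$compounds), " compounds, ",
      length(x$reactions), " directed reactions, ",
      length(x$ec_index), " ECs\n", sep = "")
  invisible(x)
}

split_field <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)[[1]]
  out <- trimws(out)
  out[nzchar(out)]
}

#' Read a reaction universe from its tabular flat files
#'
#' The reaction file is tab-separated, one reaction per line:
#' `reaction_id<TAB>ec1;ec2<TAB>sub1;sub2<TAB>prod1;prod2<TAB>direction`
#' with direction one of `>` (forward), `<` (backward) or `=` (reversible).
#' Reversible records are split into two directed reactions (suffixes
#' `__f`/`__r`) at load time; feasibility downstream is then purely "all
#' substrates present".  A compound table may sit alongside the reaction
#' file (same path with extension `.compounds.tsv`, columns
#' `id<TAB>name<TAB>pathway_class`); compounds not listed there are created
#' with their id as name.
#'
#' @param path Path to the reaction file.
#' @param compounds_path Optional explicit path to the compound table.
#' @return A [reaction_universe()].
#' @export
load_universe <- function(path, compounds_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  reactions <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L) {
      stop("parse error at line ", i, " of ", path,
           ": expected 5 tab-separated fields, got ", length(f))
    }
    id <- trimws(f[1]); dir <- trimws(f[5])
    ec <- split_field(f[2]); subs <- split_field(f[3]); prods <- split_field(f[4])
    if (!dir %in% c(">", "<", "=")) {
      stop("parse error at line ", i, " of ", path,
           ": direction must be one of > < =, got '", dir, "'")
    }
    if (!length(subs) || !length(prods)) {
      stop("parse error at line ", i, " of ", path,
           ": substrates and products must be non-empty")
    }
    if (dir == ">") {
      reactions[[length(reactions) + 1L]] <- new_reaction(id, ec, subs, prods)
    } else if (dir == "<") {
      reactions[[length(reactions) + 1L]] <- new_reaction(id, ec, prods, subs)
    } else {
      reactions[[length(reactions) + 1L]] <-
        new_reaction(paste0(id, "__f"), ec, subs, prods, TRUE, id)
      reactions[[length(reactions) + 1L]] <-
        new_reaction(paste0(id, "__r"), ec, prods, subs, TRUE, id)
    }
  }
  if (is.null(compounds_path)) {
    compounds_path <- paste0(tools::file_path_sans_ext(path), ".compounds.tsv")
  }
  mentioned <- unique(unlist(lapply(reactions,
                                    function(r) c(r$substrates, r$products))))
  if (file.exists(compounds_path)) {
    cmp <- utils::read.table(compounds_path, sep = "\t", header = FALSE,
                             quote = "", comment.char = "#",
                             col.names = c("id", "name", "pathway_class"),
                             fill = TRUE, stringsAsFactors = FALSE)
    cmp$name[!nzchar(cmp$name)] <- cmp$id[!nzchar(cmp$name)]
    cmp$pathway_class[!nzchar(cmp$pathway_class)] <- NA_character_
    extra <- setdiff(mentioned, cmp$id)
    if (length(extra)) {
      cmp <- rbind(cmp, data.frame(id = extra, name = extra,
                                   pathway_class = NA_character_))
    }
  } else {
    cmp <- data.frame(id = sort(mentioned), name = sort(mentioned),
                      pathway_class = NA_character_, stringsAsFactors = FALSE)
  }
  reaction_universe(cmp, reactions)
}

#' Write a reaction universe back to its flat files
#'
#' Directed pairs that came from one reversible record are re-joined into a
#' single `=` line, so `load_universe(write_universe(u))` round-trips up to
#' record order.
#'
#' @param universe A [reaction_universe()].
#' @param path Output path for the reaction file.
#' @param compounds_path Output path for the compound table (default:
#'   reaction path with extension `.compounds.tsv`).
#' @return `path`, invisibly.
#' @export
write_universe <- function(universe, path, compounds_path = NULL) {
  if (is.null(compounds_path)) {
    compounds_path <- paste0(tools::file_path_sans_ext(path), ".compounds.tsv")
  }
  seen <- character()
  out <- character()
  for (r in universe$reactions) {
    if (r$from_reversible) {
      if (r$parent %in% seen) next
      seen <- c(seen, r$parent)
      # emit in the forward orientation of the __f member
      fwd <- if (endsWith(r$id, "__f")) r else {
        universe$reactions[[paste0(r$parent, "__f")]]
      }
      out <- c(out, paste(fwd$parent, paste(fwd$ec, collapse = ";"),
                          paste(fwd$substrates, collapse = ";"),
                          paste(fwd$products, collapse = ";"), "=",
                          sep = "\t"))
    } else {
      out <- c(out, paste(r$id, paste(r$ec, collapse = ";"),
                          paste(r$substrates, collapse = ";"),
                          paste(r$products, collapse = ";"), ">",
                          sep = "\t"))
    }
  }
  writeLines(out, path)
  cmp <- universe$compounds
  cmp$pathway_class[is.na(cmp$pathway_class)] <- ""
  utils::write.table(cmp, compounds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an EC list (one EC per line, '#' comments allowed)
#'
#' @param path Path to the EC list file.
#' @param organism_id Organism identifier; defaults to the file stem.
#' @param genus_label Genus used for same-genus exclusion rules in summary
#'   statistics; defaults to the organism id up to the first underscore.
#' @return An object of class `genome_annotation` with fields
#'   `organism_id`, `genus_label`, `ec_set`.
#' @export
load_ec_list <- function(path, organism_id = NULL, genus_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(organism_id)) {
    organism_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- trimws(sub("#.*$", "", readLines(path)))
  ecs <- unique(lines[nzchar(lines)])
  bad <- ecs[!is_valid_ec(ecs)]
  if (length(bad)) {
    stop("malformed EC string(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  genome_annotation(organism_id, ecs, genus_label)
}

#' Construct a genome annotation
#'
#' @param organism_id Unique organism identifier.
#' @param ec_set Character vector of EC numbers.
#' @param genus_label Genus label; defaults to the organism id up to the
#'   first underscore.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(organism_id, ec_set, genus_label = NULL) {
  if (is.null(genus_label)) genus_label <- sub("_.*$", "", organism_id)
  bad <- ec_set[!is_valid_ec(ec_set)]
  if (length(bad)) {
    stop("malformed EC string(s): ", paste(bad, collapse = ", "))
  }
  structure(list(organism_id = organism_id, genus_label = genus_label,
                 ec_set = unique(ec_set)),
            class = "genome_annotation")
}

#' Write an EC list
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ec_list <- function(annotation, path) {
  writeLines(c(paste0("# ", annotation$organism_id), sort(annotation$ec_set)),
             path)
  invisible(path)
}

# Expand partial ECs (trailing '-') into the concrete universe ECs they cover.
match_ecs <- function(ec_set, universe_ecs, strict = FALSE) {
  matched <- character()
  unmapped <- character()
  for (e in ec_set) {
    if (e %in% universe_ecs) {
      matched <- c(matched, e)
    } else if (!strict && grepl("-", e, fixed = TRUE)) {
      prefix <- paste0(sub("(\\.-)+$", "", e), ".")
      hit <- universe_ecs[startsWith(universe_ecs, prefix)]
      if (length(hit)) matched <- c(matched, hit) else unmapped <- c(unmapped, e)
    } else {
      unmapped <- c(unmapped, e)
    }
  }
  list(matched = unique(matched), unmapped = unmapped)
}

#' Reconstruct an organism's metabolic network from its EC content
#'
#' Every directed reaction whose EC annotation intersects the organism's EC
#' set is included; no pathway-context filtering is applied.  Partial ECs
#' (e.g. `1.1.1.-`) match any universe EC they prefix unless
#' `strict_ec = TRUE`.  ECs absent from the universe are recorded in the
#' `unmapped_ecs` field (and reported via a message), never an error:
#' genome annotations routinely outpace any reaction catalogue.
#'
#' @param universe A [reaction_universe()].
#' @param annotation A [genome_annotation()], or a character vector of ECs.
#' @param strict_ec If `TRUE`, partial ECs only match literally.
#' @param quiet Suppress the unmapped-EC message.
#' @return An object of class `metabolic_network` with fields
#'   `organism_id`, `reactions` (named list, subset of the universe's) and
#'   `unmapped_ecs`.
#' @export
network_from_ecs <- function(universe, annotation, strict_ec = FALSE,
                             quiet = FALSE) {
  if (is.character(annotation)) {
    annotation <- genome_annotation("unnamed", annotation)
  }
  m <- match_ecs(annotation$ec_set, names(universe$ec_index), strict_ec)
  rids <- unique(unlist(universe$ec_index[m$matched], use.names = FALSE))
  if (!quiet && length(m$unmapped)) {
    message(annotation$organism_id, ": ", length(m$unmapped),
            " EC(s) not mapped to any catalogued reaction")
  }
  net <- structure(list(organism_id = annotation$organism_id,
                        reactions = universe$reactions[rids],
                        unmapped_ecs = m$unmapped),
                   class = "metabolic_network")
  if (!quiet && length(annotation$ec_set) && length(net$reactions) == 0L) {
    warning("network for ", annotation$organism_id, " is empty", call. = FALSE)
  }
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$organism_id, ": ", length(x$reactions),
      " directed reactions\n", sep = "")
  invisible(x)
}

network_compounds <- function(network) {
  unique(unlist(lapply(network$reactions,
                       function(r) c(r$substrates, r$products)),
                use.names = FALSE))
}

#' Merge metabolic networks into a combined community network
#'
#' The combined reaction set is the union of the members' sets; the
#' organism id is the ordered concatenation of member ids (joined by `+`).
#'
#' @param networks A list of `metabolic_network` objects (all derived from
#'   the same universe), or several networks as separate arguments.
#' @return A `metabolic_network` covering the union of reactions.
#' @export
merge_networks <- function(networks, ...) {
  if (inherits(networks, "metabolic_network")) {
    networks <- c(list(networks), list(...))
  }
  if (length(networks) == 0L) stop("cannot merge an empty list of networks")
  rxns <- list()
  for (n in networks) rxns[names(n$reactions)] <- n$reactions
  structure(list(organism_id = paste(vapply(networks, `[[`, "", "organism_id"),
                                     collapse = "+"),
                 reactions = rxns, unmapped_ecs = character()),
            class = "metabolic_network")
}

#' Combine reaction universes (disjoint-or-consistent union)
#'
#' Used to assemble synthetic universes from pathway fragments.
#'
#' @param ... `reaction_universe` objects.
#' @return A single [reaction_universe()].
#' @export
combine_universes <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "reaction_universe")) {
    parts <- parts[[1]]
  }
  cmp <- do.call(rbind, lapply(parts, `[[`, "compounds"))
  cmp <- cmp[!duplicated(cmp$id), , drop = FALSE]
  rxns <- list()
  for (p in parts) rxns[names(p$reactions)] <- p$reactions
  reaction_universe(cmp, unname(rxns))
}
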