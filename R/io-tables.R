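#' Read a pedigree file
#'
#' Reads a comma-delimited pedigree with mandatory header
#' `animal,sire,dam,sex,genotyped`. Unknown parents may be written as
#' `?`, `0`, `NA` or empty and are returned as `NA`. Sex is `M`/`F` (or
#' unknown); an unknown sex is inferred from usage when the animal appears
#' as a sire or dam. The pedigree must be acyclic and each known parent
#' must be used consistently (never both sire and dam; sex must match use).
#'
#' @param path path to the pedigree CSV.
#' @return A `data.frame` with columns `animal_id`, `sire_id`, `dam_id`,
#'   `sex` ("M"/"F"/NA) and `genotyped` (logical), of class `pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("animal", "sire", "dam", "sex", "genotyped")
  if (!identical(names(df), need))
    hd_parse_error(sprintf("%s: header must be exactly '%s'",
                           path, paste(need, collapse = ",")))
  unk <- function(x) { x[x %in% c("", "?", "0", "NA", ".")] <- NA; x }
  ped <- data.frame(animal_id = df$animal, sire_id = unk(df$sire),
                    dam_id = unk(df$dam), sex = toupper(unk(df$sex)),
                    genotyped = df$genotyped %in% c("1", "TRUE", "true", "T"),
                    stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$animal_id))
    hd_validation_error("duplicate animal ids in pedigree")
  if (!all(ped$sex %in% c("M", "F") | is.na(ped$sex)))
    hd_validation_error("sex must be M, F or unknown")
  self <- !is.na(ped$sire_id) & ped$sire_id == ped$animal_id |
    !is.na(ped$dam_id) & ped$dam_id == ped$animal_id
  if (any(self))
    hd_pedigree_error(sprintf("animal(s) listed as their own parent: %s",
                              paste(ped$animal_id[self], collapse = ", ")))
  sires <- unique(ped$sire_id[!is.na(ped$sire_id)])
  dams <- unique(ped$dam_id[!is.na(ped$dam_id)])
  both <- intersect(sires, dams)
  if (length(both) > 0)
    hd_validation_error(sprintf("animal(s) used both as sire and dam: %s",
                                paste(both, collapse = ", ")))
  sx <- setNames(ped$sex, ped$animal_id)
  bad_sire <- sires[sires %in% ped$animal_id & !is.na(sx[sires]) & sx[sires] != "M"]
  bad_dam <- dams[dams %in% ped$animal_id & !is.na(sx[dams]) & sx[dams] != "F"]
  if (length(bad_sire) > 0 || length(bad_dam) > 0)
    hd_validation_error(sprintf("parent sex inconsistent with usage: %s",
                                paste(c(bad_sire, bad_dam), collapse = ", ")))
  # infer sex from usage where unknown
  ped$sex[is.na(ped$sex) & ped$animal_id %in% sires] <- "M"
  ped$sex[is.na(ped$sex) & ped$animal_id %in% dams] <- "F"
  cyc <- pedigree_cycle(ped)
  if (!is.null(cyc))
    hd_pedigree_error(sprintf("pedigree contains a cycle: %s",
                              paste(cyc, collapse = " -> ")))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# iterative DFS for ancestor cycles; returns the cycle path or NULL
pedigree_cycle <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$animal_id)
  parents <- function(i) {
    p <- c(ped$sire_id[i], ped$dam_id[i])
    unname(idx[p[!is.na(p) & p %in% names(idx)]])
  }
  state <- integer(nrow(ped))  # 0 unseen, 1 in-stack, 2 done
  for (root in seq_len(nrow(ped))) {
    if (state[root] != 0) next
    stack <- list(list(node = root, todo = parents(root)))
    state[root] <- 1L
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      if (length(top$todo) == 0) {
        state[top$node] <- 2L
        stack[[length(stack)]] <- NULL
        next
      }
      nxt <- top$todo[1]
      stack[[length(stack)]]$todo <- top$todo[-1]
      if (state[nxt] == 1L) {
        path <- vapply(stack, function(s) ped$animal_id[s$node], character(1))
        return(c(path[which(vapply(stack, `[[`, integer(1), "node") == nxt):length(path)],
                 ped$animal_id[nxt]))
      }
      if (state[nxt] == 0L) {
        state[nxt] <- 1L
        stack[[length(stack) + 1]] <- list(node = nxt, todo = parents(nxt))
      }
    }
  }
  NULL
}

#' Write a pedigree file
#' @param ped a `pedigree` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(animal = ped$animal_id,
                    sire = ifelse(is.na(ped$sire_id), "?", ped$sire_id),
                    dam = ifelse(is.na(ped$dam_id), "?", ped$dam_id),
                    sex = ifelse(is.na(ped$sex), "?", ped$sex),
                    genotyped = as.integer(ped$genotyped))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a litter set
#'
#' A litter set couples one farrowing record per litter (`litter_id`,
#' `sire_id`, `dam_id`, `total_born`, `born_alive`, `weaned`) with a
#' long-format table of individual pre-weaning deaths (`litter_id`,
#' `piglet_id`, `death_day`, `cause`). A litter is `complete` when its
#' listed deaths fully account for `born_alive - weaned`; incomplete
#' death listings are allowed but flagged.
#'
#' @param litters data.frame of farrowing records.
#' @param deaths data.frame of per-piglet death records (may be empty).
#' @return An object of class `litter_set`.
#' @export
litter_set <- function(litters, deaths = NULL) {
  if (is.null(deaths))
    deaths <- data.frame(litter_id = character(0), piglet_id = character(0),
                         death_day = integer(0), cause = character(0),
                         stringsAsFactors = FALSE)
  for (col in c("total_born", "born_alive", "weaned"))
    litters[[col]] <- as.integer(litters[[col]])
  deaths$death_day <- as.integer(deaths$death_day)
  if (any(litters$born_alive > litters$total_born))
    hd_validation_error("born_alive exceeds total_born in some litter(s)")
  bad <- litters$weaned > litters$born_alive
  if (any(bad))
    hd_validation_error(sprintf("weaned exceeds born_alive in litter(s): %s",
                                paste(litters$litter_id[bad], collapse = ", ")))
  if (any(deaths$death_day < 0, na.rm = TRUE))
    hd_validation_error("negative death_day in death records")
  orphan <- setdiff(deaths$litter_id, litters$litter_id)
  if (length(orphan) > 0)
    hd_validation_error(sprintf("death records refer to unknown litter(s): %s",
                                paste(orphan, collapse = ", ")))
  ndeath <- table(factor(deaths$litter_id, levels = litters$litter_id))
  if (any(as.integer(ndeath) > litters$born_alive - litters$weaned))
    hd_validation_error("more deaths listed than born_alive - weaned for some litter(s)")
  litters$complete <- as.integer(ndeath) == litters$born_alive - litters$weaned
  structure(list(litters = litters, deaths = deaths), class = "litter_set")
}

#' @export
print.litter_set <- function(x, ...) {
  cat(sprintf("<litter_set> %d litters, %d death records (%d complete litters)\n",
              nrow(x$litters), nrow(x$deaths), sum(x$litters$complete)))
  invisible(x)
}

#' Read litter records
#'
#' Reads a comma-delimited litter table with mandatory header
#' `litter_id,sire_id,dam_id,total_born,born_alive,weaned`, plus an
#' optional companion long-format deaths table with header
#' `litter_id,piglet_id,death_day,cause` (unknown piglet/cause as `?`).
#'
#' @param path path to the litter CSV.
#' @param deaths_path optional path to the deaths CSV.
#' @return A [litter_set()] object.
#' @export
read_litters <- function(path, deaths_path = NULL) {
  lit <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("litter_id", "sire_id", "dam_id", "total_born", "born_alive", "weaned")
  if (!identical(names(lit), need))
    hd_parse_error(sprintf("%s: header must be exactly '%s'",
                           path, paste(need, collapse = ",")))
  deaths <- NULL
  if (!is.null(deaths_path)) {
    deaths <- utils::read.csv(deaths_path, stringsAsFactors = FALSE,
                              colClasses = c(litter_id = "character",
                                             piglet_id = "character",
                                             death_day = "integer",
                                             cause = "character"))
    dneed <- c("litter_id", "piglet_id", "death_day", "cause")
    if (!identical(names(deaths), dneed))
      hd_parse_error(sprintf("%s: header must be exactly '%s'",
                             deaths_path, paste(dneed, collapse = ",")))
    deaths$piglet_id[deaths$piglet_id %in% c("", "?")] <- NA
    deaths$cause[deaths$cause %in% c("", "?")] <- NA
  }
  litter_set(lit, deaths)
}

#' Write litter records (and companion deaths table)
#' @param ls a `litter_set` object.
#' @param path output CSV path for litters.
#' @param deaths_path output CSV path for deaths (optional).
#' @return `path`, invisibly.
#' @export
write_litters <- function(ls, path, deaths_path = NULL) {
  lit <- ls$litters
  utils::write.csv(lit[, c("litter_id", "sire_id", "dam_id", "total_born",
                           "born_alive", "weaned")],
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(deaths_path)) {
    d <- ls$deaths
    d$piglet_id[is.na(d$piglet_id)] <- "?"
    d$cause[is.na(d$cause)] <- "?"
    utils::write.csv(d, deaths_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
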