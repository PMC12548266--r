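#' Build a synthetic receiver network
#'
#' Creates a table of acoustic receiver stations from a compact layout
#' specification.  Each region of the study system (a lake, a connecting
#' channel, or a river) is given a habitat hydrology class and a number of
#' stations; stations within a region are interchangeable listening posts.
#'
#' @param layout Named list. Names are region labels (e.g. `"LH"`, `"SR"`);
#'   each element is a list or vector with elements `habitat` (one of
#'   `"river"`, `"lake"`, `"lake_st_clair"`) and `n` (station count >= 1).
#' @return A `data.frame` with columns `receiver_id`, `habitat`, `region`
#'   (one row per station) — the receiver classification table used by
#'   [classify_receiver()] and [build_daily_sequence()].
#' @examples
#' net <- make_network(list(LM = list(habitat = "lake", n = 3),
#'                          MR = list(habitat = "river", n = 2)))
#' table(net$habitat)
#' @export
make_network <- function(layout) {
  if (length(layout) == 0L) stopf("empty network layout")
  if (is.null(names(layout)) || any(!nzchar(names(layout))))
    stopf("every region in the layout must be named")
  rows <- lapply(names(layout), function(region) {
    el <- layout[[region]]
    habitat <- as.character(el[["habitat"]])
    n <- as.integer(el[["n"]])
    if (!habitat %in% .HABITATS)
      stopf("region '%s': habitat must be one of %s", region,
            paste(.HABITATS, collapse = ", "))
    if (is.na(n) || n < 1L) stopf("region '%s': station count must be >= 1", region)
    data.frame(
      receiver_id = sprintf("%s-%02d", region, seq_len(n)),
      habitat = habitat, region = region,
      stringsAsFactors = FALSE
    )
  })
  stations <- do.call(rbind, rows)
  habitats <- unique(stations$habitat)
  if (!"river" %in% habitats || !any(c("lake", "lake_st_clair") %in% habitats))
    stopf("layout must contain at least one river and one lake region")
  rownames(stations) <- NULL
  stations
}

#' Default synthetic study-system layout
#'
#' A compact geography echoing a Great Lakes corridor: a main lake (`LH`), a
#' shallow connecting lake with long water residence (`LSC`, classed as its
#' own hydrological unit), a connecting channel river (`SCR`) joining them,
#' and a spawning river (`SR`) draining into the main lake.
#'
#' @param stations_per_region Integer; receivers deployed per region.
#' @return Named list suitable for [make_network()].
#' @export
default_layout <- function(stations_per_region = 2L) {
  n <- as.integer(stations_per_region)
  list(
    LH  = list(habitat = "lake", n = n),
    LSC = list(habitat = "lake_st_clair", n = n),
    SCR = list(habitat = "river", n = n),
    SR  = list(habitat = "river", n = n)
  )
}

#' Default adjacency relations for the synthetic study system
#'
#' Geographic adjacency drives the substitution-cost model: states that share
#' a confluence cost 1 to substitute, all other distinct pairs cost 2.
#'
#' @param level `"region"` or `"habitat"`.
#' @return Two-column character matrix of undirected edges.
#' @export
default_adjacency <- function(level = c("region", "habitat")) {
  level <- match.arg(level)
  if (level == "region") {
    rbind(
      c("LH", "SR"),
      c("LH", "SCR"),
      c("SCR", "LSC")
    )
  } else {
    # rivers border both lake classes; the two lake classes only meet via a river
    rbind(
      c("river", "lake"),
      c("river", "lake_st_clair")
    )
  }
}

#' Look up the habitat and region of a receiver
#'
#' @param receiver_id Character scalar or vector of receiver ids.
#' @param stations Receiver classification table (as from [make_network()] or
#'   read from CSV): columns `receiver_id`, `habitat`, `region`.  Named bays
#'   are expected to already carry their parent lake's region label.
#' @return `data.frame` with columns `receiver_id`, `habitat`, `region`.
#' @export
classify_receiver <- function(receiver_id, stations) {
  idx <- match(receiver_id, stations$receiver_id)
  if (anyNA(idx))
    stopf("unknown receiver id(s): %s",
          paste(unique(receiver_id[is.na(idx)]), collapse = ", "))
  data.frame(
    receiver_id = as.character(receiver_id),
    habitat = stations$habitat[idx],
    region = stations$region[idx],
    stringsAsFactors = FALSE
  )
}
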