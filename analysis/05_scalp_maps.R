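#!/usr/bin/env Rscript
# Stage 5: two-dimensional scalp t maps — a full 27-location mapping
# session at rest and during the dexterity task, interpolated t surfaces,
# thresholded contour areas, and a figure in the style of the map plots.

library(mepmap)
dir.create("results", showWarnings = FALSE)

m <- study_map_recovery(seed = 1)
message(sprintf("hotspot node recovered: %s (max-MEP node %s, grid centre %s)",
                m$hotspot_recovered, m$hotspot_id, m$center_id))
message(sprintf("map area above t = 2.20: rest %.0f mm^2, movement %.0f mm^2 (movement/rest ratio %.1f)",
                m$area_rest, m$area_dynamic,
                m$area_dynamic / m$area_rest))

write.csv(rbind(cbind(task = "rest", m$tmap_rest$stats),
                cbind(task = "dynamic", m$tmap_dynamic$stats)),
          "results/map_t_stats.csv", row.names = FALSE)

# raster as a plain-text matrix (rows = x in mm, cols = y in mm)
ras <- m$tmap_dynamic$raster
write.table(round(ras$z, 4), "results/map_raster_dynamic.txt",
            row.names = ras$x, col.names = ras$y)

png("results/map_tmaps.png", width = 1200, height = 600, res = 120)
par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
lay <- make_layout("grid27", params = list(center = c(0, 0)))
for (nm in c("tmap_rest", "tmap_dynamic")) {
  tm <- m[[nm]]
  image(tm$raster$x, tm$raster$y, tm$raster$z,
        col = hcl.colors(64, "Blue-Red 3"), xlab = "x (mm, lateral)",
        ylab = "y (mm, anterior)",
        main = sprintf("%s: %.0f mm^2",
                       sub("tmap_", "", nm), tm$area))
  for (cl in tm$contour) lines(cl$x, cl$y, lwd = 2)
  sig <- lay$id %in% tm$significant
  points(lay$x, lay$y, pch = 21, bg = ifelse(sig, "red", "black"))
}
dev.off()
message("wrote results/map_tmaps.png")
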