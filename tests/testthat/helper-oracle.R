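# Independent oracle for the MINI reference scenario.
#
# Straight-line arithmetic over literal parameter values, written without
# reference to any package data structure or function: the worksheet a
# reviewer could redo on paper. Every quantity the pipeline produces for
# the MINI reference diet (closed trade, population 1e5) is recomputed
# here from first principles and compared in the acceptance suite.

mini_oracle <- function(population = 1e5) {
  # annual as-consumed-equivalent lb: servings/day x share x g/serving
  # / 454 g/lb x loss-waste x 365 d/yr
  lb <- function(serv, share, size, lw) serv * share * size / 454 * lw * 365

  # -- commodity demand ------------------------------------------------------
  wheat       <- lb(2,   1,       28,    1.25) * 1.37
  lettuce     <- lb(1.5, 0.6/0.9, 113.5, 1.2)        # reapportioned 2/3
  carrot      <- lb(1.5, 0.3/0.9, 113.5, 1.25)       # reapportioned 1/3
  apple       <- lb(1,   1,       113.5, 1.4)
  milk_lb     <- lb(1.5, 1,       244,   1.1)
  cheese_lb   <- lb(1,   1,       45.4,  1.1)
  fm_fat      <- milk_lb * 0.037 / 0.037 + cheese_lb * 0.30 / 0.037
  fm_nonfat   <- milk_lb * 0.086 / 0.086 + cheese_lb * 0.25 / 0.086
  fm          <- max(fm_fat, fm_nonfat)              # x1 milk processing
  beef        <- lb(0.5, 1, 113.5, 1.4) * 1.5
  chicken     <- lb(0.6, 1, 113.5, 1.3) * 1.4
  salmon_ed   <- lb(0.2, 1, 113.5, 1.2)
  salmon_farm <- salmon_ed * 0.6
  oil_prod    <- lb(2,   1, 4.54, 1.1)
  soy_oil     <- 0.6 * oil_prod
  corn_oil    <- 0.4 * oil_prod
  sweet_corn  <- lb(5,   1, 4.54, 1.05) * 2
  lard        <- lb(0.5, 1, 4.54, 1.1)

  # -- feed ------------------------------------------------------------------
  # aquaculture: feed/edible = FCR/eff = 1/0.5 = 2; E = 2*1.55 = 3.1,
  # P = 2*0.285 = 0.57; 1.6c + 1.5s = 3.1 and 0.09c + 0.48s = 0.57
  # solve exactly to c = 1, s = 1 per edible lb
  aq_corn    <- salmon_farm * 1
  aq_soymeal <- salmon_farm * 1
  beef_forage <- 6 * beef;  beef_corn <- 2 * beef;  beef_hay <- 1 * beef
  chick_corn  <- 2 * chicken; chick_soymeal <- 1 * chicken
  milk_corn   <- 0.1 * fm;  milk_hay <- 0.2 * fm;  milk_forage <- 0.3 * fm

  # -- multiuse ledger -------------------------------------------------------
  corn_oil_coprod <- sweet_corn * 0.04
  gluten_protein  <- sweet_corn * 0.25 * 0.2
  lt_coprod       <- 0.05 * beef
  corn_oil_spared <- min(corn_oil, corn_oil_coprod)
  corn_spared     <- corn_oil_spared * 25
  corn_oil_surplus <- corn_oil_coprod - corn_oil_spared
  lt_remaining    <- max(0, lard - lt_coprod)
  lt_surplus      <- max(0, lt_coprod - lard)
  soy_oil_offset  <- min(soy_oil, corn_oil_surplus + lt_surplus)
  oilseed_spared  <- soy_oil_offset * 5
  crush_protein   <- (soy_oil - soy_oil_offset) * 5 * 0.8 * 0.5
  soymeal_feed    <- chick_soymeal + aq_soymeal
  soybeans_feed   <- soymeal_feed / 0.8
  soybean_spared  <- min(soybeans_feed,
                         (gluten_protein + crush_protein) / (0.8 * 0.5))

  # -- net commodity masses and land -----------------------------------------
  corn_total <- sweet_corn + beef_corn + chick_corn + milk_corn + aq_corn +
    corn_oil * 25 - corn_spared
  soy_total  <- soybeans_feed + soy_oil * 5 - oilseed_spared - soybean_spared
  hay_total  <- beef_hay + milk_hay
  forage_total <- beef_forage + milk_forage

  acres <- c(wheat = wheat / 2700, lettuce = lettuce / 30000,
             carrot = carrot / 30000, apple = apple / 20000,
             corn_grain = corn_total / 10000, soybeans = soy_total / 3000,
             hay = hay_total / 5000)
  cult        <- sum(acres[c("wheat", "lettuce", "carrot", "apple",
                             "corn_grain", "soybeans")])
  forage_land <- acres[["hay"]]
  grazing     <- forage_total / 2000

  # -- availability, grazing adjustment, capacity ----------------------------
  ci         <- 60000 / 50000
  productive <- 50000 + 10000
  prop_cult  <- 48000 / 60000
  avail_cult <- productive * prop_cult / ci - 2000
  avail_all  <- productive - 2000
  avail_graz <- 200000 + 40000

  RA <- avail_graz / avail_all
  RR <- grazing / (cult / ci + forage_land)
  RY <- 2000 / 4000
  cug    <- if (RR > RA) (grazing - RA * (cult / ci + forage_land)) / (RA + RY) else 0
  offset <- cug * RY

  pf1 <- avail_cult / cult
  pf2 <- avail_all / (cult / ci + forage_land + cug)
  pf3 <- (avail_all + avail_graz) /
    (cult / ci + forage_land + grazing + cug - offset)
  cc  <- min(pf1, pf2, pf3) / population
  land_pc <- cult / ci + (forage_land + cug) + (grazing - offset)

  # -- amendments (N, P2O5, K2O, S, pesticides, irrigation per acre) ---------
  rates <- rbind(
    wheat      = c(60, 25, 20, 5, 1, 0.2),
    corn_grain = c(120, 50, 60, 10, 2, 0.5),
    soybeans   = c(10, 20, 30, 5, 1.5, 0.3),
    lettuce    = c(100, 40, 50, 5, 3, 1.5),
    carrot     = c(80, 30, 40, 5, 2, 1),
    apple      = c(50, 20, 40, 5, 4, 1.2),
    hay        = c(30, 15, 25, 3, 0.3, 0.1))
  colnames(rates) <- c("N", "P2O5", "K2O", "S", "pesticides", "irrigation")
  amend <- colSums(acres[rownames(rates)] * rates)

  # -- nutrients (per-serving composition x daily servings) ------------------
  energy <- 2*80 + 1*10 + 0.5*25 + 1*60 + 1.5*103 + 1*45 + 0.5*180 +
    0.6*140 + 0.2*130 + 2*40 + 5*16 + 0.5*37
  protein <- 2*3 + 1*1 + 0.5*1 + 1*0 + 1.5*8 + 1*3 + 0.5*22 + 0.6*26 +
    0.2*22 + 2*0 + 5*0 + 0.5*0

  list(
    commodities = list(
      wheat = wheat, lettuce = lettuce, carrot = carrot, apple = apple,
      fm_fat = fm_fat, fm_nonfat = fm_nonfat, fm = fm, beef = beef,
      chicken = chicken, salmon_farmed = salmon_farm,
      salmon_wild = salmon_ed * 0.4, soy_oil = soy_oil,
      corn_oil = corn_oil, sweet_corn = sweet_corn, lard = lard),
    feed = list(corn = beef_corn + chick_corn + milk_corn + aq_corn,
                soymeal = soymeal_feed, hay = hay_total,
                forage = forage_total),
    ledger = list(corn_oil_coproduced = corn_oil_coprod,
                  gluten_protein = gluten_protein,
                  lard_tallow_coproduced = lt_coprod,
                  corn_oil_spared = corn_oil_spared,
                  corn_spared = corn_spared,
                  lard_tallow_remaining = lt_remaining,
                  lard_tallow_surplus = lt_surplus,
                  oilseed_spared = oilseed_spared,
                  crush_protein = crush_protein,
                  soybean_spared = soybean_spared),
    net = list(corn = corn_total, soybeans = soy_total),
    land = list(acres = acres, cultivated = cult, forage = forage_land,
                grazing = grazing),
    avail = list(ci = ci, productive = productive, prop_cult = prop_cult,
                 avail_cult = avail_cult, avail_all = avail_all,
                 avail_graz = avail_graz),
    grazing_adj = list(RA = RA, RR = RR, RY = RY, cug = cug,
                       offset = offset),
    output = list(pf = c(pf1, pf2, pf3), carrying_capacity = cc,
                  land_pc = land_pc, amendments = amend,
                  energy_kcal = energy, protein_g = protein))
}
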