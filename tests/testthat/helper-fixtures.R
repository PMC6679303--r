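# shared fixtures: all synthetic, built in code at test time

base_crop <- crop_params()
base_soil <- soil_params()
base_climate <- climate_spec()

# one fixed weather realisation covering a full season
season_weather <- generate_weather(base_climate, "2016-10-10", 255, seed = 4242)

# a single constant weather day
make_wd <- function(tmin = 10, tmax = 20, rain = 0, irrigation = 0,
                    radiation = 15) {
  list(tmin = tmin, tmax = tmax, rain = rain, irrigation = irrigation,
       radiation = radiation)
}

# short benign weather table for fast scheme runs
short_weather <- function(n = 80, seed = 7, start = "2017-03-01") {
  generate_weather(base_climate, start, n, seed = seed)
}
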