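# Synthetic demonstration knowledge base (6 species).
# Generated by odofuzz::generate_knowledge_base(); the trapezoids and
# colour matrices are NOT expert knowledge about any real fauna.
schema_version: '1.0'
colours:
- yellow
- orange
- red
- green
- blue
- brown
- black
biotopes:
- lake
- puddle
- canal
- garden_pool
- quarry
- wetland
- brook
- headwaters_and_spring
- organic_soil_wetland
- pond
- river
- oxbow_lake
- reservoir_in_valley
- terrestrial_habitat
- other
colour_similarity:
  yellow:
    yellow: 1.0
    orange: 0.0
    red: 0.0
    green: 0.0
    blue: 0.0
    brown: 0.0
    black: 0.0
  orange:
    yellow: 0.0
    orange: 1.0
    red: 0.5
    green: 0.0
    blue: 0.0
    brown: 0.0
    black: 0.0
  red:
    yellow: 0.0
    orange: 0.5
    red: 1.0
    green: 0.0
    blue: 0.0
    brown: 0.0
    black: 0.0
  green:
    yellow: 0.0
    orange: 0.0
    red: 0.0
    green: 1.0
    blue: 0.3
    brown: 0.0
    black: 0.0
  blue:
    yellow: 0.0
    orange: 0.0
    red: 0.0
    green: 0.3
    blue: 1.0
    brown: 0.0
    black: 0.0
  brown:
    yellow: 0.0
    orange: 0.0
    red: 0.0
    green: 0.0
    blue: 0.0
    brown: 1.0
    black: 0.0
  black:
    yellow: 0.0
    orange: 0.0
    red: 0.0
    green: 0.0
    blue: 0.0
    brown: 0.0
    black: 1.0
species:
- species_id: species_01
  suborder: zygoptera
  seasonality:
    a: 175.0
    b: 180.0
    c: 228.0
    d: 238.0
  altitude:
    a: 1049.0
    b: 1231.0
    c: 1375.0
    d: 1455.0
  colours:
    male:
      additive:
        orange: 1.0
        red: 1.0
      exclusion:
        green: 0.0
        black: 0.0
    female:
      additive:
        green: 1.0
      exclusion:
        black: 0.0
- species_id: species_02
  suborder: anisoptera
  seasonality:
    a: 144.0
    b: 160.0
    c: 213.0
    d: 225.0
  altitude:
    a: 831.0
    b: 915.0
    c: 1243.0
    d: 1304.0
  colours:
    male:
      additive:
        orange: 1.0
        red: 1.0
        blue: 1.0
      exclusion:
        green: 0.0
    female:
      additive:
        green: 1.0
      exclusion: {}
- species_id: species_03
  suborder: anisoptera
  seasonality:
    a: 179.0
    b: 192.0
    c: 252.0
    d: 269.0
  altitude:
    a: 960.0
    b: 1059.0
    c: 1391.0
    d: 1500.0
  colours:
    male:
      additive:
        blue: 1.0
      exclusion:
        green: 0.0
        brown: 0.0
    female:
      additive:
        yellow: 1.0
        red: 1.0
        black: 1.0
      exclusion: {}
- species_id: species_04
  suborder: anisoptera
  seasonality:
    a: 226.0
    b: 239.0
    c: 281.0
    d: 291.0
  altitude:
    a: 519.0
    b: 676.0
    c: 806.0
    d: 900.0
  colours:
    male:
      additive:
        black: 1.0
      exclusion:
        yellow: 0.0
        brown: 0.0
    female:
      additive:
        yellow: 1.0
        brown: 1.0
        black: 1.0
      exclusion:
        orange: 0.0
- species_id: species_05
  suborder: anisoptera
  seasonality:
    a: 188.0
    b: 207.0
    c: 261.0
    d: 266.0
  altitude:
    a: 786.0
    b: 888.0
    c: 1091.0
    d: 1225.0
  colours:
    male:
      additive:
        yellow: 1.0
      exclusion:
        blue: 0.0
    female:
      additive:
        red: 1.0
        blue: 1.0
        brown: 1.0
      exclusion: {}
- species_id: species_06
  suborder: anisoptera
  seasonality:
    a: 80.0
    b: 97.0
    c: 143.0
    d: 149.0
  altitude:
    a: 220.0
    b: 375.0
    c: 507.0
    d: 584.0
  colours:
    male:
      additive:
        orange: 1.0
      exclusion: {}
    female:
      additive:
        yellow: 1.0
        red: 1.0
        brown: 1.0
      exclusion: {}
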