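# Versioned conversion table: categorical FFQ responses -> quantitative traits.
# Frequency classes share a label set; values are times/week unless noted.
version: 1
classes:
  frequency:
    aliases: [meat, fish, cheese, frequency]
    unit: times/week
    levels:
      - label: "Never"
        value: 0
      - label: "Less than once a week"
        value: 0.5
      - label: "Once a week"
        value: 1
      - label: "2-4 times a week"
        value: 3
      - label: "5-6 times a week"
        value: 5.5
      - label: "Once or more daily"
        value: 7
  alcohol:
    aliases: [alcohol]
    unit: times/week
    levels:
      - label: "Never"
        value: 0
      - label: "Special occasions only"
        value: 0.125
      - label: "One to three times a month"
        value: 0.5
      - label: "One to two times a week"
        value: 1.5
      - label: "Three to four times a week"
        value: 3.5
      - label: "Five to six times a week"
        value: 5.5
      - label: "Daily or almost daily"
        value: 7
milk:
  types: ["never/rarely", "full cream", "semi-skimmed", "skimmed"]
  coefficients:
    cereal_bowls: 100
    coffee_cups: 25
    tea_cups: 35
quantitative_units:
  fresh_fruit: pieces/day
  dried_fruit: pieces/day
  cooked_veg: tablespoons/day
  raw_veg: tablespoons/day
  coffee: cups/day
  tea: cups/day
missing_labels: ["do not know", "prefer not to answer"]
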