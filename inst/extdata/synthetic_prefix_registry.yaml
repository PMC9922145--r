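# SYNTHETIC example registry: categories 3-6, 8 and 10 carry placeholder
# prefixes (50-55) for simulation only; they are NOT real survey food codes.
provenance: Literature-derived umami sodium-reduction rates by UK Nutrient Databank
  food category
categories:
- id: 1
  name: Cheese
  main_groups:
  - 14
  prefixes: []
  lower_pct: 54.0
  upper_pct: 100.0
  substances: MSG
- id: 2
  name: Sausage
  main_groups:
  - 22
  - 30
  prefixes: []
  lower_pct: 17.0
  upper_pct: 75.0
  substances: MSG, CDG, Inosinate
- id: 3
  name: Chicken broth
  main_groups: []
  prefixes:
  - '50'
  lower_pct: 11.0
  upper_pct: 38.0
  substances: MSG, CDG
- id: 4
  name: Salted fish
  main_groups: []
  prefixes:
  - '51'
  lower_pct: 30.0
  upper_pct: 40.0
  substances: MSG, Inosinate
- id: 5
  name: Miso
  main_groups: []
  prefixes:
  - '52'
  lower_pct: 15.0
  upper_pct: 35.0
  substances: MSG, Inosinate, Guanylate
- id: 6
  name: Soy sauce
  main_groups: []
  prefixes:
  - '53'
  lower_pct: 40.0
  upper_pct: 61.0
  substances: MSG, Inosinate, Guanylate
- id: 7
  name: Snack
  main_groups:
  - 42
  prefixes: []
  lower_pct: 51.0
  upper_pct: 51.0
  substances: MSG, Inosinate, Guanylate
- id: 8
  name: Vegetable soup
  main_groups: []
  prefixes:
  - '54'
  lower_pct: 17.0
  upper_pct: 40.0
  substances: Glutamates, CDG
- id: 9
  name: Potato chips
  main_groups:
  - 38
  prefixes: []
  lower_pct: 30.0
  upper_pct: 30.0
  substances: MSG
- id: 10
  name: Salted vegetable
  main_groups: []
  prefixes:
  - '55'
  lower_pct: 55.0
  upper_pct: 55.0
  substances: MSG
- id: 11
  name: Butter
  main_groups:
  - 17
  prefixes: []
  lower_pct: 100.0
  upper_pct: 100.0
  substances: MSG
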