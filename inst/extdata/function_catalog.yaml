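# Default therapeutic-function catalog for gut LBP design.
# Each entry: function_id, display_name, marker_groups (AND over groups,
# OR within a group; matching is case-insensitive substring on product text
# or exact term id), optional min_groups (default: all groups required).
- function_id: butyrate
  display_name: Butyrate synthesis
  marker_groups:
    - ["butyryl-CoA dehydrogenase"]
    - ["butyrate kinase", "butyryl-CoA:acetate CoA-transferase", "butyryl-CoA transferase"]
- function_id: propionate
  display_name: Propionate synthesis
  marker_groups:
    - ["methylmalonyl-CoA decarboxylase", "propionate CoA-transferase", "propionyl-CoA", "propanediol dehydratase"]
- function_id: gaba
  display_name: Gamma-aminobutyrate (GABA) synthesis
  marker_groups:
    - ["glutamate decarboxylase", "GABA antiporter"]
- function_id: indole
  display_name: Indole synthesis from tryptophan
  marker_groups:
    - ["tryptophanase", "tryptophan indole-lyase"]
- function_id: siderophore_synthesis
  display_name: Siderophore synthesis
  marker_groups:
    - ["yersiniabactin synthesis", "enterobactin synthase", "siderophore biosynthesis"]
- function_id: siderophore_uptake
  display_name: Heterologous siderophore uptake
  marker_groups:
    - ["ferrichrome uptake", "enterobactin uptake", "aerobactin uptake", "siderophore transporter", "ferric siderophore receptor"]
- function_id: siderophore
  display_name: Siderophore activity (synthesis or uptake)
  marker_groups:
    - ["yersiniabactin synthesis", "enterobactin synthase", "siderophore biosynthesis",
       "ferrichrome uptake", "enterobactin uptake", "aerobactin uptake",
       "siderophore transporter", "ferric siderophore receptor"]
- function_id: antimicrobial
  display_name: Antimicrobial (bacteriocin/lantibiotic) synthesis
  marker_groups:
    - ["bacteriocin", "lantibiotic", "lanthipeptide", "lactococcin", "linocin"]
- function_id: cgh
  display_name: Choloylglycine hydrolase (bile-salt deconjugation)
  marker_groups:
    - ["choloylglycine hydrolase", "bile salt hydrolase"]
- function_id: hsd_3a
  display_name: 3a-hydroxysteroid dehydrogenase
  marker_groups:
    - ["3alpha-hydroxysteroid dehydrogenase"]
- function_id: hsd_3b
  display_name: 3b-hydroxysteroid dehydrogenase
  marker_groups:
    - ["3beta-hydroxysteroid dehydrogenase"]
- function_id: hsd_7a
  display_name: 7a-hydroxysteroid dehydrogenase
  marker_groups:
    - ["7alpha-hydroxysteroid dehydrogenase"]
- function_id: hsd_7b
  display_name: 7b-hydroxysteroid dehydrogenase
  marker_groups:
    - ["7beta-hydroxysteroid dehydrogenase"]
- function_id: dh_7a
  display_name: 7a-dehydratase (secondary bile acid synthesis)
  marker_groups:
    - ["7alpha-dehydratase", "bile acid 7alpha-dehydroxylation"]
- function_id: dh_7b
  display_name: 7b-dehydratase
  marker_groups:
    - ["7beta-dehydratase"]
- function_id: dh_3a
  display_name: 3a-hydroxy bile acid-CoA-ester-3 dehydrogenase
  marker_groups:
    - ["3alpha-hydroxy bile acid-CoA-ester-3 dehydrogenase"]
- function_id: oxo_3_5a
  display_name: 3-oxo-5a-steroid-4-dehydrogenase
  marker_groups:
    - ["3-oxo-5alpha-steroid 4-dehydrogenase"]
- function_id: lcd
  display_name: L-carnitine hydratase
  marker_groups:
    - ["L-carnitine hydratase", "carnitine dehydratase"]
- function_id: sbs
  display_name: Sodium-bile acid symporter
  marker_groups:
    - ["sodium/bile acid symporter", "bile acid:Na+ symporter"]
- function_id: bile_salt
  display_name: Bile-salt deconjugation / bile acid conversion (any enzyme)
  marker_groups:
    - ["choloylglycine hydrolase", "bile salt hydrolase",
       "3alpha-hydroxysteroid dehydrogenase", "3beta-hydroxysteroid dehydrogenase",
       "7alpha-hydroxysteroid dehydrogenase", "7beta-hydroxysteroid dehydrogenase",
       "7alpha-dehydratase", "7beta-dehydratase",
       "3alpha-hydroxy bile acid-CoA-ester-3 dehydrogenase",
       "3-oxo-5alpha-steroid 4-dehydrogenase", "L-carnitine hydratase",
       "sodium/bile acid symporter", "taurine uptake"]
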