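# Functional-class vocabulary: 25 classes in priority order, keywords are
# case-insensitive whole words/phrases scanned against hit descriptions.
# "unknown conserved" and "unknown" are similarity-defined and carry no
# keywords.
@uninformative: hypothetical, uncharacterized, unknown, unnamed, predicted protein
secreted: secreted, salivary, venom allergen, basic tail, antigen 5, gene-10
metalloprotease: metalloprotease, metalloproteinase, reprolysin, astacin, neprilysin, ADAM, ADAMTS, leishmanolysin
protease inhibitor: protease inhibitor, kunitz, serpin, cystatin, trypsin inhibitor, thyropin, alpha-2-macroglobulin, TIL domain, hirudin
lipocalin: lipocalin, histamine-binding, moubatin, biogenic amine-binding, tick salivary peptide
mucin: mucin, peritrophin, chitin-binding
proteolysis: cathepsin, legumain, trypsin, chymotrypsin, aminopeptidase, carboxypeptidase, serine protease, dipeptidase, peptidase
energy metabolism: NADH dehydrogenase, ATP synthase, cytochrome c oxidase, cytochrome b, succinate dehydrogenase, malate dehydrogenase, citrate synthase, enolase, aldolase, pyruvate kinase
carbohydrate metabolism: glucosidase, galactosidase, amylase, chitinase, trehalase, mannosidase, glycogen, glycosyl hydrolase
lipid metabolism: lipase, phospholipase, apolipoprotein, fatty acid synthase, sterol carrier, acyl-CoA, sphingomyelinase, ceramidase
protein synthesis: ribosomal protein, elongation factor, initiation factor, tRNA synthetase, tRNA ligase
protein modification: kinase, phosphatase, methyltransferase, glycosyltransferase, acetyltransferase, prolyl hydroxylase, peptidylglycine
protein export: signal peptidase, translocase, signal recognition particle, oligosaccharyltransferase, SEC61, protein disulfide isomerase
proteasome machinery: proteasome, ubiquitin, SUMO, cullin, F-box
transcription machinery: RNA polymerase, transcription factor, zinc finger, homeobox, mediator complex
nuclear regulation: histone, chromatin, helicase, topoisomerase, condensin
transporters and channels: transporter, ion channel, aquaporin, ATP-binding cassette, symporter, antiporter, porin
cytoskeletal: actin, tubulin, myosin, dynein, kinesin, spectrin, troponin
extracellular matrix: collagen, laminin, fibronectin, cuticle protein, dumpy
immunity: defensin, lysozyme, microplusin, lectin, thioester-containing protein, peptidoglycan recognition, ixodidin
oxidant metabolism: glutathione S-transferase, cytochrome P450, superoxide dismutase, catalase, peroxidase, thioredoxin, sulfotransferase, carboxylesterase
heme and iron: ferritin, transferrin, heme-binding protein, hemelipoglycoprotein, iron-sulfur
storage: vitellogenin, hexamerin, larval serum protein
signal transduction: GTPase, G protein, calmodulin, 14-3-3 protein, adenylate cyclase, phosphodiesterase
unknown conserved:
unknown:
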