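order,common_name,species,pigment_class,pigment_lambda_max,lambda_t50,axial_length,group_label,omt_uv_known,notes
Psittaciformes,Bourke's parrot,Neopsephotus bourkii,UVS,NA,334,NA,parrot,TRUE,pigment inferred from phylogeny
Psittaciformes,budgerigar,Melopsittacus undulatus,UVS,371,320,NA,parrot,TRUE,
Psittaciformes,crimson rosella,Platycercus elegans,UVS,363,319,NA,parrot,TRUE,
Passeriformes,common starling,Sturnus vulgaris,UVS,362,337,NA,UVS-passerine,TRUE,OMT averaged from separate components
Passeriformes,common blue tit,Cyanistes caeruleus,UVS,372,316,NA,UVS-passerine,TRUE,
Passeriformes,great tit,Parus major,UVS,NA,314,NA,UVS-passerine,TRUE,pigment inferred from phylogeny
Passeriformes,common blackbird,Turdus merula,UVS,373,343,NA,UVS-passerine,TRUE,
Passeriformes,song thrush,Turdus philomelos,UVS,NA,335,NA,UVS-passerine,TRUE,pigment inferred from phylogeny
Passeriformes,Gouldian finch,Erythrura gouldiae,UVS,370,315,NA,UVS-passerine,TRUE,
Passeriformes,cut-throat finch,Amadina fasciata,UVS,370,316,NA,UVS-passerine,TRUE,
Passeriformes,white-headed munia,Lonchura maja,UVS,373,317,NA,UVS-passerine,TRUE,
Passeriformes,plum-headed finch,Neochmia modesta,UVS,373,314,NA,UVS-passerine,TRUE,
Passeriformes,Timor zebra finch,Taeniopygia guttata,UVS,359,321,NA,UVS-passerine,TRUE,
Passeriformes,rook,Corvus frugilegus,VS,NA,365,NA,VS-passerine,TRUE,pigment inferred from phylogeny
Passeriformes,common magpie,Pica pica,VS,NA,370,NA,VS-passerine,TRUE,pigment inferred from phylogeny
Passeriformes,green catbird,Ailuroedus crassirostris,VS,406,340,NA,VS-passerine,TRUE,
Passeriformes,great bowerbird,Chlamydera nuchalis,VS,404,349,NA,VS-passerine,TRUE,
Passeriformes,regent bowerbird,Sericulus chrysocephalus,VS,408,349,NA,VS-passerine,TRUE,
Passeriformes,satin bowerbird,Ptilonorhynchus violaceus,VS,410,344,NA,VS-passerine,TRUE,
Passeriformes,spotted bowerbird,Chlamydera maculata,VS,NA,351,NA,VS-passerine,TRUE,
Strigiformes,burrowing owl,Athene cunicularia,VS,NA,359,NA,owl,TRUE,VS grouping uncertain; no sws1 pigment found in owls
Strigiformes,northern long-eared owl,Asio otus,VS,NA,356,NA,owl,TRUE,VS grouping uncertain; no sws1 pigment found in owls
Strigiformes,tawny owl,Strix aluco,VS,NA,353,NA,owl,TRUE,VS grouping uncertain; no sws1 pigment found in owls
Strigiformes,boreal owl,Aegolius funereus,VS,NA,335,NA,owl,TRUE,VS grouping uncertain; no sws1 pigment found in owls
Falconiformes,Eurasian buzzard,Buteo buteo,VS,405,375,NA,raptor,TRUE,
Falconiformes,Eurasian sparrowhawk,Accipiter nisus,VS,405,369,NA,raptor,TRUE,
Falconiformes,red kite,Milvus milvus,VS,NA,394,NA,raptor,TRUE,pigment inferred from phylogeny
Falconiformes,common kestrel,Falco tinnunculus,VS,NA,379,NA,raptor,TRUE,pigment inferred from phylogeny
Struthioniformes,ostrich,Struthio camelus,VS,405,369,NA,other,FALSE,OMT unknown at very short wavelengths
Galliformes,domestic chicken,Gallus gallus domesticus,VS,418,351,NA,landfowl,TRUE,
Galliformes,wild turkey,Meleagris gallopavo,VS,420,355,NA,landfowl,TRUE,
Galliformes,Indian peafowl,Pavo cristatus,VS,421,364,NA,landfowl,TRUE,
Apodiformes,common swift,Apus apus,VS,NA,388,NA,other,TRUE,pigment inferred from phylogeny
Apodiformes,green-backed firecrown,Sephanoides sephaniodes,VS,NA,310,NA,other,TRUE,pigment inferred from phylogeny
Columbiformes,rock dove,Columba livia,VS,404,337,NA,other,TRUE,
Procellariiformes,wedge-tailed shearwater,Puffinus pacificus,VS,406,335,NA,other,TRUE,
Podicipediformes,great crested grebe,Podiceps cristatus,VS,NA,390,NA,other,TRUE,
Anseriformes,mallard,Anas platyrhynchos,VS,420,371,NA,other,FALSE,OMT unknown at very short wavelengths
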