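stim_1,stim_2,stim_3,stim_4,stim_5,stim_6,stim_7,stim_8,stim_9,stim_10
40.614046535652534,26.22612211551646,88.13801086758171,62.683037144282565,76.91915971989725,87.05486740471119,72.06135349975018,115.07426169972523,91.66477731800855,59.34850039032149
10.746238188355921,21.06979868518727,45.82711812942901,35.08005213337769,39.75726817289683,35.493554194277486,53.55566308663236,27.326372727800702,54.6658216547407,45.08728519181667
27.211144323955406,43.38753277236073,25.847831673134746,36.71539911605524,43.007255912688535,27.741287306688687,41.112311259627056,39.94598993997338,48.71812585744738,51.777909405380186
17.995620877549623,37.11607044441386,47.362316244830396,36.31988727852883,28.727512191144918,46.8221637962837,58.148834447177016,75.49815927856015,44.69761752119886,54.275985374888336
33.69301580290231,25.140683734870628,34.31898634336738,41.24295571679247,50.78488137666291,31.117057068262792,39.553019922791734,50.18790485409368,40.572673081757166,47.51787381451035
11.171941972438074,32.27844368855904,15.572205942626821,31.330810567658776,30.06869733873862,51.11676977673564,44.450251061437676,49.57285967329817,55.714632300217055,30.09341010786521
1.0131568960107669,32.7109791909909,23.63784415360918,94.08152653439045,67.7589920148467,34.458319109371004,44.76512357062226,56.24664922723577,34.79071074404961,72.45340035364053
29.364923997203707,30.2701557851055,50.20055369878252,20.39022276143711,30.072793791097016,76.5451396074062,68.20776932276387,19.616391641884686,10.650168338905072,38.55620349252375
38.286159579982716,31.596939272165653,31.556431306383605,58.19197868707569,48.728295973856696,19.807393020034187,27.25822723231763,60.028093712809714,51.201778017623994,28.968508511196443
73.93809650515183,40.944020256003114,53.68994881058634,41.75591646589755,31.22489613074874,111.24624713819796,59.13167334246762,60.19899127828012,73.84345815536574,117.262047610521
20.241266254869206,20.716556035758824,27.461991583176797,49.70620580793909,75.02882222590429,23.371894790165896,39.90070628248175,44.463598542835086,20.085413957743615,87.65877779811137
47.92533047870594,63.92861508649289,0.9657285871578926,64.15335829033558,89.35910329362451,107.0066152520151,86.65450997160535,93.23797870379518,65.01080858777614,141.41578944804778
45.42104721654784,71.00113531991063,104.29738705861656,28.5678076073438,86.04649378326538,43.71783490131716,55.5720911239937,101.55942035054721,99.80378160118772,47.241286722436875
22.032698767035633,42.177251072833066,29.35856917382537,61.69668002777913,52.09052438223896,31.422252100414717,63.356562428949196,61.71371310043876,53.2173811520697,37.225827276607745
43.6460405980971,28.94199113533377,70.19221683858804,68.75629858317264,94.74115298440307,58.21325331849768,54.400549717904134,27.875067725476775,92.81437625604735,97.86466508563039
9.421162462507553,42.145868608124076,44.25352825234672,55.39085102952938,57.6600038539479,62.665426644290804,64.406281475932,59.602405614752485,43.77794581757275,46.10034342427421
9.102839691626464,21.4541177855323,34.30527222009744,39.297387637644256,57.21223124241617,41.02887674103816,15.121749033222365,34.69683359973781,56.99274878569538,58.27381742972806
11.217209288631175,30.51672645181211,30.804252039849537,56.198764817637084,56.52862380170928,56.361141623316875,50.44206002319217,67.18115718243713,54.473210181065355,16.39096946769057
10.529872640301175,42.406559201535735,60.23644791314645,28.809027563552917,57.87170072615881,99.90103757692964,59.904061202414475,52.783819361116315,45.60544691239127,49.238721046747
13.991409196767822,71.83615142087963,34.7319061114904,73.14614617213039,70.96848195655586,70.9901043807497,108.09752391592275,50.40863993652872,46.60655908709252,56.950625407110664
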