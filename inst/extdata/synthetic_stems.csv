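quadrat_id,species,bd_cm,height_m,crown_w1_m,crown_w2_m
4,Cydonia oblonga,0.892862484529911,0.69109577621122,0.380528009048193,0.276447924822012
3,Cydonia oblonga,0.527973941220838,0.697584634282971,0.417332831527247,0.470883982331049
3,Cydonia oblonga,0.0981533393608714,0.436311830110918,0.229060372480012,0.111548894423989
4,Cydonia oblonga,0.560473150957112,0.340890559590888,0.164300061804121,0.137096027100151
3,Cydonia oblonga,2.91339458528968,1.23498215839265,0.840869761485999,0.748469108430377
3,Cydonia oblonga,0.065876926758537,0.0530476098893742,0.140093209311759,0
2,Cydonia oblonga,0.0237960842139758,0.05,0.0905519594167979,0.033689016983821
3,Cydonia oblonga,1.41811281077986,0.359110860665573,0.12960182951228,0.382950866178185
4,Cydonia oblonga,4.75807325512049,2.01622077856046,1.20926143610039,1.24756572608181
3,Cydonia oblonga,1.34221451184171,0.598891620802372,0.30401903035244,0.294920727564801
1,Cydonia oblonga,1.36307131353578,0.584658709321793,0.212502015704163,0.420729207764868
2,Cydonia oblonga,0.875548393096909,0.886387152686384,0.553603616803687,0.42272702840106
4,Cydonia oblonga,1.64496298969742,0.813124408861993,0.526668676496509,0.465704141574963
3,Cydonia oblonga,1.73899931974964,0.994753716987206,0.740687636940722,0.654271404065832
4,Cydonia oblonga,2.21064061091793,0.940821699073005,0.684054784972119,0.511147404876517
4,Cydonia oblonga,3.10948612790297,1.3164163770319,0.947169349234095,0.732013397531045
2,Cydonia oblonga,0.340289630077592,0.119872862476483,0.112705056727119,0.0744947081373698
4,Cydonia oblonga,0.700964634523044,0.581513893318964,0.38884552118143,0.284135611896828
2,Cydonia oblonga,4.39074097987817,1.88056206170069,1.14572853202458,1.09315012203063
4,Cydonia oblonga,0.293076656373252,0.416052549283595,0.170536225432738,0.340772976542155
2,Cydonia oblonga,3.5093847327383,1.36912197100097,0.727503042046608,0.655455835740877
4,Cydonia oblonga,0.698985754365247,0.780232886647756,0.59052623106098,0.390645463333695
4,Cydonia oblonga,0.887271859741405,0.616449702631842,0.405872119859249,0.672541748671829
3,Cydonia oblonga,1.99704816993337,1.0786852630893,0.671170829758697,0.577089407865095
2,Cydonia oblonga,0.594625530839292,0.640927796736318,0.484050269006323,0.306421360486582
2,Cydonia oblonga,1.64544400854866,0.636420520048191,0.437281976940233,0.476459024818668
3,Cydonia oblonga,3.14469009255651,1.17328594285318,0.724711619393931,0.737655268699955
1,Cydonia oblonga,0.784076994635946,0.707280582710748,0.536204767862444,0.260470386343949
1,Cydonia oblonga,6.30550574109351,2.15263368070208,1.2729174738864,1.23089532329619
2,Cydonia oblonga,6.04582786531968,2.11248872537877,1.34820117845615,0.99107392534664
2,Spiraea chinensis,1.0475196892775,0.47252029103717,0.0784987369391411,0.129196902365171
3,Spiraea chinensis,0.0606933587598105,0.376734206156185,0.254837595451284,0.0939804330403071
2,Spiraea chinensis,2.42013126025862,0.981166543658149,0.624894468112697,0.521117775737799
2,Spiraea chinensis,0.077910119539783,0.350500228075095,0.0416260344550184,0.173599594249973
1,Spiraea chinensis,0.770939614543266,0.241858814465059,0.269832268904871,0.0937280705838101
4,Spiraea chinensis,1.89325243621307,0.847211231033419,0.331307450415664,0.412401342313969
1,Spiraea chinensis,0.125233450049938,0.400981058353011,0.262872221557007,0.228422267773211
1,Spiraea chinensis,0.407057707855857,0.217195557762645,0.0742652913493234,0.196911049769459
3,Spiraea chinensis,0.143857004063165,0.456311026478737,0.222973659666856,0.397658597788787
4,Spiraea chinensis,2.93912539025198,1.29759086885033,0.684671212491798,0.896948599564406
4,Spiraea chinensis,1.73973016437147,0.527622356574512,0.480138352368687,0.466409563074415
3,Spiraea chinensis,0.0259579283864616,0.0732283984970838,0,0.0150266035628156
1,Spiraea chinensis,3.30457106268346,0.908654901351633,0.629114302758574,0.737561662658168
4,Spiraea chinensis,0.464767094047344,0.343554813952328,0.144973359185471,0.257984133426851
4,Spiraea chinensis,0.0907724635841888,0.0911192411813601,0.0174998475725113,0.10233064037752
3,Spiraea chinensis,1.14327859166052,0.295849322072784,0.125986197413944,0.207769967898268
3,Spiraea chinensis,0.231709592233157,0.307363883534213,0.150241469092901,0.266541601107399
4,Spiraea chinensis,0.75117918369028,0.521700894879622,0.381412414985639,0.352278462957654
1,Spiraea chinensis,0.230039187057013,0.216971339960986,0.210017050668222,0
4,Spiraea chinensis,0.20082982583202,0.182959463017325,0.0297952635857101,0.0228859294566948
4,Spiraea chinensis,0.0111630179442333,0.263074243882787,0.180807570818716,0
3,Spiraea chinensis,1.56481184244014,0.81247713477986,0.65684107392721,0.482431552674539
3,Spiraea chinensis,1.69443398643276,0.747357034587442,0.37156712378333,0.578365508387799
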