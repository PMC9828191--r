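individual_id,absolute_fitness,flower_number,plant_height,inflorescence_length,linalool,beta_ocimene,alpha_pinene,limonene,eugenol,benzyl_acetate,methyl_benzoate,phenylacetaldehyde
1,1.31693465119809,13.1557835898088,13.1500011104541,10.5119790174224,1.16489343934835,0.659753853468565,3.0487777346088,0.997503038707022,0.8922786392374,0.342728345170511,7.87971269802335,0.792961253013879
2,0.692251784842881,11.1924682186369,10.2499044604396,11.3048950326421,1.65802202168293,0.573545269460039,7.17923591499852,5.91195893309367,0.54075723161966,0.0989947211616597,4.06491272326542,0.780670526213235
3,-0.053750720194573,7.65284611825728,5.23329264286592,10.2476802628864,0.787707928111718,5.45067343892945,1.93994782101626,1.61178311064572,2.64499033863329,2.34542769128283,1.1467578309066,0.222074121414156
4,0.994522542006857,9.68871493021936,10.5645382608842,9.59218564293363,1.05706621861929,0.874329098160554,1.97001460842473,0.225436537156979,0.51554456533555,3.95185773844407,0.511237714678837,0.839403606319438
5,0.607773668634733,6.16218035946032,5.21423075484465,5.3553270398237,1.85900883498022,0.553947773350739,4.27389229117603,0.819339851954039,1.56130124246882,0.598371190050854,1.26613634361845,0.332586853411609
6,0.520521550642372,9.60948230777873,8.33523067613394,12.6984843854713,0.74452437730285,0.549774827125639,1.49707372446883,2.05172893460557,1.31992176822429,0.690146407225826,0.895937946736721,1.23317281135207
7,0.784837476262517,4.81534466010803,10.9706426478987,11.6915727457202,1.0738877091592,0.689020175187444,1.84825567841122,4.88772995251832,0.564364471767559,0.0143467652935037,11.4835253293244,2.77637848265561
8,1.34537029812811,12.6280043343961,11.9629615490921,9.74073351123962,1.98350375691079,1.95541413384442,3.01333009838609,1.70437120919209,3.24579610396358,2.37919759231051,0.590871508499687,0.103235558350276
9,0.981460845266876,8.72891399793573,11.7014458226909,9.97852353721526,0.974341309735883,1.51351803352995,3.04348131194662,2.10807793034481,1.7702459488881,0.372039393490181,5.03546995014895,0.24276686601823
10,1.42653525312579,9.14004232261162,10.3269774902692,6.6107586167851,0.935492121668452,0.923847413832859,0.714458518582726,0.618449419695976,0.928355385713379,5.16785817283369,0.854426676196654,0.836812239346012
11,1.0885057790629,9.66136333539607,9.68823947679487,10.9075317676018,1.21568863158225,1.1495331424333,2.88239771233762,0.648845012977596,4.31130435309435,12.0402405558962,0.993676148538865,0.070566901424634
12,1.39867368308191,11.2244363479783,8.60385452708043,12.9535062680274,1.77201042408664,0.739601393362867,1.77735022243152,1.83276165995703,0.429747151549548,2.18281235934969,2.19712831961867,0.613134567466049
13,1.1308409971135,11.3566803544454,13.4460898546315,8.06891338961547,0.6066911514763,1.06647715944856,0.2628271754654,0.244420633914022,0.682866557177424,2.33712843995419,0.259443619220159,6.49505371241656
14,1.29595624241308,11.1359039449433,10.4266459315384,8.91341153694294,1.67422347790377,0.40238412649469,2.00088523974453,0.579903450713388,0.367170137782156,0.16254797540249,3.42056343209165,1.86017047619284
15,0.668316947418188,8.85491479214775,8.29209640675693,8.15134869935404,0.501847514051681,0.27455948293333,0.291991999300474,2.64718736315199,0.549943651538791,0.138348601300131,0.867697675231951,5.86336555931655
16,1.12550910133908,7.27341748744332,10.8327657118163,8.29852534707443,1.35822202429821,1.42269757191859,2.43940564178993,2.85088087254437,0.663822790986317,0.0485596135069856,6.2335315177105,1.78553376126223
17,1.45604361600336,9.2225555113242,11.8166693528158,6.4652664973354,1.29981264118166,0.783470569636707,1.12702480686836,0.321768333515902,0.616484937984392,0.525746355939328,2.15304845682336,2.78589224322117
18,1.69197201836752,10.5558282649011,13.7834272823928,11.9313463605147,0.640895361024884,1.00671793458333,0.744395598497291,0.675368392908747,1.55479492589919,2.42084351549408,0.605404496351198,0.509107382348527
19,0.513569146604661,8.35383775685595,8.35570579454155,6.39706151888728,1.25058897795563,0.978509663048946,0.543249951955849,1.18555994350311,0.534219154130784,0.398520309042634,1.41655083020266,4.493704517899
20,0.434246200687281,9.86231813104307,9.2129671657925,9.74019913358168,0.274537332693129,2.14941846034772,0.530817815929002,1.22159488802266,1.52430302356375,1.9952253625214,0.454527085480553,0.940266225461451
21,0.83785911352637,7.6646753477404,8.50530157958202,10.2169546387538,0.985536226521981,0.590669806985305,0.179356128661107,0.171353100620008,1.37432248326735,4.08541213813871,0.334596827595584,0.536632230456319
22,0.690548116700772,9.98338197156879,9.27830590760737,9.46169388203165,0.657849424139873,7.18870057717452,2.62712929628384,2.51508460167188,3.66585778478683,1.33619564301555,1.82841466891135,0.0434931025954748
23,1.48352513040749,10.2577108031948,9.37782597784235,11.571801358776,0.639141093711606,1.49146178999722,1.6304153858586,1.39808557145309,0.566062240351528,1.50957288012939,0.668645247228608,0.799314230124788
24,0.653840845936039,9.70824874307799,9.34835799671044,9.73455687021234,0.570370065327893,0.893744749282161,0.641610830273622,1.29362653400354,2.55936202804684,1.68188916784316,1.22841466982499,0.431017254088414
25,1.24511805502751,9.67217808652786,12.6524714473438,9.33415243166181,0.769611843137365,1.12678029022611,1.68042807134495,1.15644686678315,1.41803926076582,1.42427361410898,0.541961068618121,0.897000093600835
26,1.0888090140272,13.5271040055698,9.72731295938042,11.9509092338029,0.560103108993592,3.53069180268929,0.713068257845874,4.20591502362033,3.03082511663598,5.16346961319589,1.19985363178732,0.51793427456883
27,1.34241719074753,11.5251730248366,9.71697550622173,9.48129040457012,0.273323734129921,2.56519663565539,0.438686590413201,0.6241199030046,1.5153484305441,1.06852533574138,1.43062262637651,5.40569416696252
28,1.4961572755578,12.2228621614613,11.9118188525983,14.244800518401,2.1730243570292,0.777869448308265,2.22823312192641,0.107916808577105,0.594653358187154,1.57217609371582,1.5803326400993,1.86298193811843
29,0.700810366475177,8.15358609434034,11.5920048871491,9.90739322876496,0.566870294858684,2.36629506171099,10.9857914643606,2.20827198513159,1.31770466542402,0.390953827185625,3.92102503061115,0.24653441521243
30,0.66634444647749,10.3286836768559,8.62551157737269,11.3418107815522,0.720872672690813,0.776981166914693,0.272037277888206,0.250579780704013,1.51367477183442,4.7684502022964,0.0980143911311541,1.24738920510244
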