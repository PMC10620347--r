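sung	sing
sang	sing
went	go
gone	go
made	make
done	do
children	child
men	man
women	woman
feet	foot
teeth	tooth
mice	mouse
ran	run
said	say
told	tell
taught	teach
bought	buy
brought	bring
thought	think
caught	catch
took	take
taken	take
gave	give
given	give
got	get
gotten	get
kept	keep
left	leave
felt	feel
found	find
chose	choose
chosen	choose
spoke	speak
spoken	speak
wrote	write
written	write
drew	draw
drawn	draw
sat	sit
stood	stand
came	come
saw	see
seen	see
knew	know
known	know
grew	grow
grown	grow
built	build
swam	swim
swum	swim
rode	ride
ridden	ride
ate	eat
eaten	eat
slept	sleep
wore	wear
worn	wear
better	good
best	good
drove	drive
driven	drive
perhaps	perhaps
always	always
towards	towards
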